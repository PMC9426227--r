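#' Construct an OTU count table
#'
#' The `otu_table` is the universal input of the pipeline: a matrix of
#' non-negative integer read counts with OTUs as rows and samples as columns,
#' optionally carrying a semicolon-ranked taxonomy lineage per OTU.
#'
#' @param counts numeric matrix of whole, non-negative counts
#'   (OTUs x samples) with unique row and column names.
#' @param taxonomy optional character vector of lineage strings, one per OTU
#'   (named or in row order), ranks separated by `;`.
#'
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer matrix) and `taxonomy` (named character vector or `NULL`).
#' @examples
#' m <- matrix(c(5, 0, 1, 2, 0, 7), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("OTU", 1:3), c("s1", "s2")))
#' x <- otu_table(m)
#' grand_total(x)
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have OTU row names and sample column names")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicate OTU id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (!is.numeric(counts))
    stop("counts must be numeric")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at OTU '%s', sample '%s': %s",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 format(counts[bad[1, , drop = FALSE]])))
  zero <- colnames(counts)[colSums(counts) == 0]
  if (length(zero))
    stop("sample(s) with zero total count: ", paste(zero, collapse = ", "))
  storage.mode(counts) <- "double"  # keeps exact whole numbers, avoids int overflow
  if (!is.null(taxonomy)) {
    taxonomy <- as.character(taxonomy)
    if (length(taxonomy) != nrow(counts))
      stop("taxonomy must have one entry per OTU")
    names(taxonomy) <- rownames(counts)
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples, %s reads%s\n",
              nrow(x$counts), ncol(x$counts),
              format(grand_total(x), big.mark = ","),
              if (is.null(x$taxonomy)) "" else ", with taxonomy"))
  invisible(x)
}

#' @rdname otu_table
#' @param x an `otu_table`.
#' @export
grand_total <- function(x) sum(x$counts)

#' Pooled relative abundance per OTU
#'
#' Relative abundance of OTU i is its total count across all samples divided
#' by the grand total of the table (pooled, not a per-sample mean).
#'
#' @param x an `otu_table`.
#' @return named numeric vector summing to 1.
#' @export
pooled_relative_abundance <- function(x) {
  tot <- rowSums(x$counts)
  tot / sum(tot)
}

#' Read an OTU table from a tab-separated file
#'
#' Expects a header row of sample ids, first column of OTU ids (the header of
#' that column is conventionally `#OTU_ID`), and an optional trailing
#' `taxonomy` column. No quoting, UTF-8.
#'
#' @param path path to the TSV file.
#' @return a validated [otu_table()]; row and column order preserved.
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                           quote = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("OTU table needs an id column and >=1 sample")
  ids <- as.character(raw[[1]])
  has_tax <- tolower(names(raw)[ncol(raw)]) == "taxonomy"
  count_cols <- seq(2, ncol(raw) - as.integer(has_tax))
  counts <- as.matrix(raw[, count_cols, drop = FALSE])
  rownames(counts) <- ids
  otu_table(counts, taxonomy = if (has_tax) raw[[ncol(raw)]] else NULL)
}

#' Write an OTU table to a tab-separated file
#'
#' @param x an `otu_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(`#OTU_ID` = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$taxonomy)) df$taxonomy <- unname(x$taxonomy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove rare OTUs by pooled relative abundance
#'
#' Retains OTU i iff `total_i / grand_total >= min_rel_abund`, i.e. only OTUs
#' with relative abundance strictly below the threshold are removed (an OTU
#' sitting exactly on the threshold is kept). The sample set is unchanged.
#'
#' @param x an `otu_table`.
#' @param min_rel_abund fraction in `[0, 1)`; the default `1e-4` removes OTUs
#'   below 0.01\% relative abundance.
#' @return filtered `otu_table`.
#' @export
filter_rare <- function(x, min_rel_abund = 1e-4) {
  if (!is.numeric(min_rel_abund) || min_rel_abund < 0 || min_rel_abund >= 1)
    stop("min_rel_abund must be in [0, 1)")
  keep <- pooled_relative_abundance(x) >= min_rel_abund
  if (!any(keep))
    stop("all OTUs removed; lower min_rel_abund (currently ",
         format(min_rel_abund), ")")
  otu_table(x$counts[keep, , drop = FALSE],
            taxonomy = if (is.null(x$taxonomy)) NULL else x$taxonomy[keep])
}

#' Species groups by pooled relative abundance
#'
#' Builds the three groups used throughout the analysis: `all` OTUs, `core`
#' OTUs (pooled relative abundance strictly above `core_thresh`) and
#' `dominant` OTUs (strictly above `dominant_thresh`). The default core
#' threshold of 10\% is taken literally and is ecologically unusual (it yields
#' fewer members than "dominant"); both thresholds are configurable.
#'
#' @param x an `otu_table`.
#' @param core_thresh,dominant_thresh fractions in `(0, 1)`.
#' @return named list of `species_group` objects (`all`, `core`, `dominant`),
#'   each a list with `name`, `member_otu_ids`, `threshold`.
#' @export
species_groups <- function(x, core_thresh = 0.10, dominant_thresh = 0.005) {
  for (th in c(core_thresh, dominant_thresh))
    if (!is.numeric(th) || th <= 0 || th >= 1)
      stop("thresholds must be in (0, 1)")
  rel <- pooled_relative_abundance(x)
  grp <- function(name, threshold) {
    ids <- if (is.na(threshold)) names(rel) else names(rel)[rel > threshold]
    if (!is.na(threshold) && length(ids) == 0)
      message("species group '", name, "' is empty at threshold ",
              format(threshold))
    structure(list(name = name, member_otu_ids = ids, threshold = threshold),
              class = "species_group")
  }
  list(all = grp("all", NA_real_),
       core = grp("core", core_thresh),
       dominant = grp("dominant", dominant_thresh))
}

#' @export
print.species_group <- function(x, ...) {
  cat(sprintf("species_group '%s': %d OTUs%s\n", x$name,
              length(x$member_otu_ids),
              if (is.na(x$threshold)) ""
              else sprintf(" (rel. abundance > %s)", format(x$threshold))))
  invisible(x)
}

# position-based rank parsing of semicolon lineages; anything missing or blank
# at the requested rank becomes "unclassified"
.tax_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
                "species")

.taxon_at <- function(lineage, level) {
  idx <- match(level, .tax_ranks)
  parts <- strsplit(lineage, ";", fixed = TRUE)
  vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[a-z]__", "", p)  # tolerate greengenes-style prefixes
    if (length(p) >= idx && nzchar(p[idx]) &&
        !grepl("^unclassified$|^unknown$", p[idx], ignore.case = TRUE))
      p[idx]
    else "unclassified"
  }, character(1))
}

#' Ranked relative-abundance summary
#'
#' Pools counts at the requested taxonomic level, ranks taxa by pooled
#' relative abundance, and reports the top `top_n` together with per-sample
#' proportions; remaining taxa are lumped into an `other` row. This is the
#' numeric backbone of percentage-stacking displays of community composition.
#'
#' @param x an `otu_table`; taxonomy is required unless `level = "otu"`.
#' @param level `"otu"` or one of the seven standard ranks
#'   (`"kingdom"` ... `"species"`).
#' @param top_n number of taxa to report individually.
#' @return data.frame with columns `taxon`, `rel_abund` (pooled) and one
#'   proportion column per sample; per-sample columns each sum to 1.
#' @export
relative_abundance_summary <- function(x, level = "otu", top_n = 30) {
  level <- match.arg(level, c("otu", .tax_ranks))
  if (level == "otu") {
    m <- x$counts
  } else {
    if (is.null(x$taxonomy))
      stop("taxonomy is required for level '", level, "'")
    taxon <- .taxon_at(x$taxonomy, level)
    m <- rowsum(x$counts, taxon)
  }
  rel <- rowSums(m) / sum(m)
  ord <- order(rel, decreasing = TRUE)
  m <- m[ord, , drop = FALSE]
  rel <- rel[ord]
  if (nrow(m) > top_n) {
    head_m <- m[seq_len(top_n), , drop = FALSE]
    other <- colSums(m[-seq_len(top_n), , drop = FALSE])
    m <- rbind(head_m, other = other)
    rel <- c(rel[seq_len(top_n)], other = sum(rel[-seq_len(top_n)]))
  }
  prop <- sweep(m, 2, colSums(x$counts), "/")
  data.frame(taxon = rownames(m), rel_abund = unname(rel), prop,
             check.names = FALSE, row.names = NULL)
}

#' Per-habitat OTU presence sets and Venn region counts
#'
#' An OTU is "present" in a habitat iff its summed count over that habitat's
#' samples is positive. Returns the per-habitat presence sets and the count of
#' OTUs in every non-empty region of the habitat Venn partition (a region is
#' the set of OTUs present in exactly that combination of habitats, so regions
#' are disjoint and their union is every OTU present anywhere).
#'
#' @param x an `otu_table`.
#' @param meta sample metadata (see [read_sample_metadata()]); every sample of
#'   `x` must be mapped to a habitat.
#' @return list with `sets` (named list of OTU id vectors per habitat) and
#'   `regions` (data.frame `region`, `n_habitats`, `count`), where `region`
#'   is an `&`-joined habitat combination.
#' @export
venn_counts <- function(x, meta) {
  hab <- habitat_of(meta, colnames(x$counts))
  pooled <- t(rowsum(t(x$counts), hab))      # otus x habitats
  present <- pooled > 0
  sets <- lapply(colnames(present), function(h) rownames(present)[present[, h]])
  names(sets) <- colnames(present)
  any_present <- rowSums(present) > 0
  pattern <- apply(present[any_present, , drop = FALSE], 1, function(p)
    paste(colnames(present)[p], collapse = "&"))
  tab <- table(pattern)
  regions <- data.frame(region = names(tab),
                        n_habitats = lengths(strsplit(names(tab), "&",
                                                      fixed = TRUE)),
                        count = as.integer(tab), row.names = NULL)
  regions <- regions[order(regions$n_habitats, regions$region), ]
  rownames(regions) <- NULL
  list(sets = sets, regions = regions)
}
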