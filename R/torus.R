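#' Mean per-cell relative abundance of an OTU in a habitat
#'
#' The habitat statistic of the torus test: the OTU's relative abundance in
#' each lattice cell (cell count / cell sequencing depth) averaged over the
#' cells the map labels with the habitat. Depth normalisation matters because
#' sequencing depth, unlike stem counts in forest-plot censuses, varies by
#' sample.
#'
#' @param otu_row numeric vector of counts per cell (row-major cell order).
#' @param map label matrix (one of the [translations()]).
#' @param habitat habitat label to average over.
#' @param cell_depths total reads per cell, same order as `otu_row`; defaults
#'   to all-1 (i.e. `otu_row` already holds relative abundances).
#' @return mean per-cell relative abundance (a single number).
#' @export
habitat_stat <- function(otu_row, map, habitat, cell_depths = NULL) {
  cells <- which(as.vector(map) == habitat)
  if (!length(cells)) stop("habitat '", habitat, "' absent from map")
  if (is.null(cell_depths)) cell_depths <- rep(1, length(otu_row))
  mean(otu_row[cells] / cell_depths[cells])
}

# comparisons between statistics of different maps tolerate floating-point
# jitter so that mathematically tied subsets (same cell multiset summed in a
# different order) are counted as ties
.stat_tol <- 1e-12

#' Torus-translation habitat-association test
#'
#' Classifies every OTU x habitat pair as positively associated, negatively
#' associated, or neutral. The observed statistic is [habitat_stat()] under
#' the true habitat map; the null distribution holds the species distribution
#' fixed and recomputes the statistic under every non-identity torus
#' translation of the map (all shifts of four images; see [translations()]),
#' which preserves the spatial autocorrelation of both the species and the
#' habitats. One-sided p-values use the add-one permutation rule with ties
#' counted inclusively on both sides:
#' `p_pos = (# null >= observed + 1) / (# null + 1)` and analogously `p_neg`,
#' so p-values are never 0 and `p_pos + p_neg > 1`.
#'
#' No correction is applied across OTUs by default; set `p_adjust = "BH"` for
#' a Benjamini-Hochberg option applied per tail.
#'
#' @param x an `otu_table`, already filtered (see [filter_rare()]).
#' @param meta sample metadata mapping samples to lattice cells.
#' @param lattice optional [habitat_lattice()]; built from `meta` by default.
#' @param alpha per-tail significance level in `(0, 0.5]`.
#' @param harms use the 0.025 per-tail level of the original forest-plot
#'   formulation instead of `alpha`.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame of class `association_result` with columns `otu_id`,
#'   `habitat`, `observed`, `p_pos`, `p_neg`, `classification`
#'   (`positive`/`negative`/`neutral`); attributes `alpha`, `n_null`.
#' @export
torus_test <- function(x, meta, lattice = NULL, alpha = 0.05, harms = FALSE,
                       p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 0.5)
    stop("alpha must be in (0, 0.5]")
  if (harms) alpha <- 0.025
  meta <- sample_metadata(meta)
  if (is.null(lattice)) lattice <- build_lattice(meta)
  if (is.null(lattice$samples))
    stop("lattice carries no sample ids; build it from metadata")
  cell_samples <- as.vector(lattice$samples)
  if (anyNA(cell_samples))
    stop("every lattice cell must reference a sample")
  miss <- setdiff(cell_samples, colnames(x$counts))
  if (length(miss))
    stop("lattice sample(s) missing from the OTU table: ",
         paste(miss, collapse = ", "))

  counts <- x$counts[, cell_samples, drop = FALSE]
  rel <- sweep(counts, 2, colSums(counts), "/")   # per-cell relative abundance
  maps <- translations(lattice)
  habitats <- sort(unique(as.vector(lattice$labels)))
  n_maps <- length(maps)
  n_cells <- length(cell_samples)

  # one column of weights per (map, habitat): 1/n_h on that habitat's cells
  W <- matrix(0, n_cells, n_maps * length(habitats))
  for (m in seq_len(n_maps)) {
    lab <- as.vector(maps[[m]])
    for (h in seq_along(habitats)) {
      cells <- lab == habitats[h]
      W[cells, (m - 1L) * length(habitats) + h] <- 1 / sum(cells)
    }
  }
  S <- rel %*% W                                  # otus x (maps * habitats)
  dim(S) <- c(nrow(rel), length(habitats), n_maps)
  obs <- S[, , 1, drop = FALSE]
  dim(obs) <- dim(S)[1:2]
  n_null <- n_maps - 1L
  ge <- le <- matrix(0L, nrow(rel), length(habitats))
  for (m in 2:n_maps) {
    ge <- ge + (S[, , m] >= obs - .stat_tol)
    le <- le + (S[, , m] <= obs + .stat_tol)
  }
  p_pos <- (ge + 1L) / (n_null + 1L)
  p_neg <- (le + 1L) / (n_null + 1L)

  res <- data.frame(
    otu_id = rep(rownames(x$counts), times = length(habitats)),
    habitat = rep(habitats, each = nrow(x$counts)),
    observed = as.vector(obs),
    p_pos = as.vector(p_pos),
    p_neg = as.vector(p_neg),
    stringsAsFactors = FALSE)
  if (p_adjust == "BH") {
    res$p_pos <- stats::p.adjust(res$p_pos, "BH")
    res$p_neg <- stats::p.adjust(res$p_neg, "BH")
  }
  res$classification <- ifelse(res$p_pos <= alpha, "positive",
                        ifelse(res$p_neg <= alpha, "negative", "neutral"))
  attr(res, "alpha") <- alpha
  attr(res, "n_null") <- n_null
  class(res) <- c("association_result", "data.frame")
  res
}

#' Per-OTU specialist calls from association results
#'
#' An OTU is a specialist if it is positively associated with at least one
#' habitat. The assigned habitat is the positive habitat with the smallest
#' `p_pos` (ties broken by the larger observed statistic).
#'
#' @param results an `association_result` from [torus_test()].
#' @return data.frame with one row per OTU: `otu_id`, `specialist`,
#'   `n_positive`, `positive_habitats` (comma-joined), `best_habitat`.
#' @export
specialists <- function(results) {
  sp <- split(seq_len(nrow(results)), results$otu_id)
  rows <- lapply(sp, function(i) {
    pos <- i[results$classification[i] == "positive"]
    best <- NA_character_
    if (length(pos)) {
      o <- pos[order(results$p_pos[pos], -results$observed[pos])]
      best <- results$habitat[o[1]]
    }
    data.frame(otu_id = results$otu_id[i[1]],
               specialist = length(pos) > 0,
               n_positive = length(pos),
               positive_habitats = paste(results$habitat[pos], collapse = ","),
               best_habitat = best,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise association results the way the study tables report them
#'
#' Per kingdom and per species group, tallies the tested OTUs, the number and
#' percentage positively associated with at least one habitat, the percentage
#' neutral to every habitat, and per-habitat positive percentages (an OTU may
#' be positive for several habitats, so per-habitat percentages can sum to
#' more than the any-habitat percentage). If a forest-type map is given,
#' additionally reports — pooled across kingdoms — the percentage of OTUs
#' whose positive habitats fall in each forest type (each OTU counted once
#' per forest type).
#'
#' @param results an `association_result`, optionally with a `kingdom`
#'   column (e.g. `"bacteria"`/`"fungi"`); rows must cover every tested
#'   OTU x habitat pair.
#' @param groups optional result of [species_groups()] (or any named list of
#'   OTU id vectors) to summarise per group in addition to `all`.
#' @param forest_type_map optional named character vector mapping habitat ->
#'   forest type (e.g. `c(LAG = "coniferous", ...)`).
#' @return list of class `association_summary` with data.frames `overall`,
#'   `per_habitat` and (optionally) `forest_types`. Percentages are reported
#'   unrounded on the 0-100 scale.
#' @export
summarize_associations <- function(results, groups = NULL,
                                   forest_type_map = NULL) {
  results <- as.data.frame(results)
  if (is.null(results$kingdom)) results$kingdom <- "all"
  if (!is.null(groups))
    groups <- lapply(groups, function(g)
      if (is.list(g) && !is.null(g$member_otu_ids)) g$member_otu_ids else g)
  overall <- NULL; per_hab <- NULL
  for (kg in unique(results$kingdom)) {
    rk <- results[results$kingdom == kg, ]
    grp_list <- c(list(all = unique(rk$otu_id)),
                  if (!is.null(groups)) groups[names(groups) != "all"])
    for (gn in names(grp_list)) {
      rg <- rk[rk$otu_id %in% grp_list[[gn]], ]
      n <- length(unique(rg$otu_id))
      if (n == 0) next
      pos <- rg[rg$classification == "positive", ]
      neg <- rg[rg$classification == "negative", ]
      n_pos <- length(unique(pos$otu_id))
      n_neutral <- n - length(unique(c(pos$otu_id, neg$otu_id)))
      overall <- rbind(overall, data.frame(
        kingdom = kg, group = gn, n_tested = n,
        n_positive = n_pos, pct_positive = 100 * n_pos / n,
        n_negative = length(unique(neg$otu_id)),
        pct_neutral = 100 * n_neutral / n, stringsAsFactors = FALSE))
      for (h in sort(unique(rg$habitat))) {
        nh <- length(unique(pos$otu_id[pos$habitat == h]))
        per_hab <- rbind(per_hab, data.frame(
          kingdom = kg, group = gn, habitat = h, n_positive = nh,
          pct_positive = 100 * nh / n, stringsAsFactors = FALSE))
      }
    }
  }
  out <- list(overall = overall, per_habitat = per_hab)
  if (!is.null(forest_type_map)) {
    pooled_n <- length(unique(paste(results$kingdom, results$otu_id)))
    pos <- results[results$classification == "positive", ]
    pos$forest_type <- unname(forest_type_map[pos$habitat])
    ft <- NULL
    for (type in unique(unname(forest_type_map))) {
      ids <- unique(paste(pos$kingdom, pos$otu_id)[
        !is.na(pos$forest_type) & pos$forest_type == type])
      ft <- rbind(ft, data.frame(
        forest_type = type, n_otus = length(ids), n_pooled = pooled_n,
        pct = 100 * length(ids) / pooled_n, stringsAsFactors = FALSE))
    }
    out$forest_types <- ft
  }
  class(out) <- c("association_summary", "list")
  out
}

#' @export
print.association_summary <- function(x, ...) {
  cat("Association summary\n\n")
  print(x$overall, row.names = FALSE)
  if (!is.null(x$forest_types)) {
    cat("\nForest-type preferences (pooled kingdoms)\n")
    print(x$forest_types, row.names = FALSE)
  }
  invisible(x)
}
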