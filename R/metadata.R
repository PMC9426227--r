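#' Validate sample metadata
#'
#' Sample metadata maps each sequenced sample to a habitat (plant community
#' type) and to a quadrat position on the rectangular sampling lattice.
#'
#' @param meta data.frame with columns `sample_id`, `habitat`, `grid_row`,
#'   `grid_col`, `replicate`; grid coordinates are 0-based integers.
#' @return the validated data.frame (character/integer columns coerced).
#' @export
sample_metadata <- function(meta) {
  need <- c("sample_id", "habitat", "grid_row", "grid_col", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  meta <- as.data.frame(meta)[need]
  meta$sample_id <- as.character(meta$sample_id)
  meta$habitat <- as.character(meta$habitat)
  for (col in c("grid_row", "grid_col", "replicate")) {
    v <- meta[[col]]
    if (!is.numeric(v) || any(v != round(v)) || any(v < 0))
      stop("metadata column '", col, "' must hold non-negative integers")
    meta[[col]] <- as.integer(v)
  }
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  key <- paste(meta$grid_row, meta$grid_col)
  if (anyDuplicated(key))
    stop("duplicate (grid_row, grid_col) in metadata: ",
         key[duplicated(key)][1])
  if (any(table(meta$habitat) < 1)) stop("every habitat needs >= 1 sample")
  meta
}

#' Read sample metadata from TSV
#' @param path TSV with columns sample_id, habitat, grid_row, grid_col,
#'   replicate.
#' @return validated metadata data.frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sample_metadata(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_sample_metadata
#' @param meta validated metadata.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# habitat label for each of the given sample ids, erroring on unmapped samples
habitat_of <- function(meta, sample_ids) {
  idx <- match(sample_ids, meta$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from metadata: ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  meta$habitat[idx]
}

#' Construct an environment table
#'
#' Holds quantitative environmental variables per sample, each tagged into one
#' of the three explanatory groups used by the variation partitioning:
#' `topography`, `soil`, `light`.
#'
#' @param values numeric matrix (samples x variables) with sample row names
#'   and variable column names; no missing values.
#' @param var_group character vector, one tag per variable, each one of
#'   `"topography"`, `"soil"`, `"light"`.
#' @return object of class `env_table`: list with `values` and `var_group`.
#' @export
env_table <- function(values, var_group) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("env values need sample row names and variable column names")
  if (!is.numeric(values) || anyNA(values))
    stop("env values must be numeric with no missing entries")
  var_group <- as.character(var_group)
  if (length(var_group) != ncol(values))
    stop("var_group must have one tag per variable")
  bad <- setdiff(unique(var_group), c("topography", "soil", "light"))
  if (length(bad))
    stop("unknown variable group(s): ", paste(bad, collapse = ", "))
  names(var_group) <- colnames(values)
  structure(list(values = values, var_group = var_group), class = "env_table")
}

#' @export
print.env_table <- function(x, ...) {
  cat(sprintf("env_table: %d samples x %d variables (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$var_group)),
                            table(x$var_group)), collapse = ", ")))
  invisible(x)
}

#' Read/write an environment table
#'
#' The file format has a two-row header: row 1 holds `sample_id` plus the
#' variable names, row 2 (first field `#group`) the group tag of each
#' variable; data rows follow.
#'
#' @param path TSV path.
#' @return an [env_table()].
#' @export
read_env_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3) stop("env table needs 2 header rows plus data")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  grp <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (length(grp) != length(hdr))
    stop("group-tag row must align with the header row")
  body <- utils::read.delim(text = paste(lines[-2], collapse = "\n"),
                            check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(body[, -1, drop = FALSE])
  rownames(values) <- as.character(body[[1]])
  env_table(values, grp[-1])
}

#' @rdname read_env_table
#' @param env an `env_table`.
#' @export
write_env_table <- function(env, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(env$values)), collapse = "\t"), con)
  writeLines(paste(c("#group", unname(env$var_group)), collapse = "\t"), con)
  utils::write.table(data.frame(sample_id = rownames(env$values), env$values,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Split an environment table into its variable groups
#' @param env an `env_table`.
#' @return named list of numeric matrices (`topography`, `soil`, `light`),
#'   omitting empty groups.
#' @export
env_groups <- function(env) {
  out <- lapply(c(topography = "topography", soil = "soil", light = "light"),
                function(g) env$values[, env$var_group == g, drop = FALSE])
  out[vapply(out, ncol, integer(1)) > 0]
}
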