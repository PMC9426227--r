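#' Construct a habitat lattice
#'
#' The habitat lattice is the object the torus-translation test translates: a
#' gap-free rectangular grid of quadrats, each cell carrying a habitat label
#' and (optionally) the id of the sample taken in that quadrat.
#'
#' @param labels character matrix of habitat labels (rows x cols), no missing
#'   cells.
#' @param samples optional character matrix of the same shape holding sample
#'   ids (`NA` for unsampled cells).
#' @return object of class `habitat_lattice`: list with `labels`, `samples`.
#' @export
habitat_lattice <- function(labels, samples = NULL) {
  labels <- as.matrix(labels)
  mode(labels) <- "character"
  if (anyNA(labels) || any(!nzchar(labels)))
    stop("every lattice cell must carry a habitat label")
  if (!is.null(samples)) {
    samples <- as.matrix(samples)
    mode(samples) <- "character"
    if (!all(dim(samples) == dim(labels)))
      stop("samples matrix must match the label matrix in shape")
  }
  structure(list(labels = labels, samples = samples),
            class = "habitat_lattice")
}

#' @export
print.habitat_lattice <- function(x, ...) {
  cat(sprintf("habitat_lattice: %d x %d cells, %d habitats\n",
              nrow(x$labels), ncol(x$labels),
              length(unique(as.vector(x$labels)))))
  print(x$labels, quote = FALSE)
  invisible(x)
}

#' Build the lattice implied by sample metadata
#'
#' Uses the `grid_row`/`grid_col` coordinates; the grid must be gap-free
#' (every cell of the bounding rectangle sampled exactly once) because the
#' torus translation slides the whole habitat map.
#'
#' @param meta validated sample metadata.
#' @return a [habitat_lattice()] with `samples` filled in.
#' @export
build_lattice <- function(meta) {
  meta <- sample_metadata(meta)
  nr <- max(meta$grid_row) + 1L
  nc <- max(meta$grid_col) + 1L
  if (nr * nc != nrow(meta))
    stop(sprintf("grid has gaps: %d x %d cells but %d samples",
                 nr, nc, nrow(meta)))
  labels <- matrix(NA_character_, nr, nc)
  samples <- matrix(NA_character_, nr, nc)
  idx <- cbind(meta$grid_row + 1L, meta$grid_col + 1L)
  labels[idx] <- meta$habitat
  samples[idx] <- meta$sample_id
  habitat_lattice(labels, samples)
}

#' Lay habitats out on a lattice
#'
#' Assigns `n_habitats * reps_per_habitat` cells to habitats in contiguous
#' blocks. Layouts:
#' \describe{
#'   \item{`brick`}{(default, requires 3 replicates and an even habitat
#'     count) pairs of habitats tile 2x3 bricks as L-triominoes on an
#'     `n_habitats x 3` grid. The L-patches have no mirror or rotation
#'     symmetry on the torus, so every one of the `4*rows*cols` null maps of
#'     the torus test selects a distinct cell set; straight replicate runs,
#'     by contrast, are reproduced exactly by the mirrored/rotated images,
#'     which caps attainable significance on small regular grids.}
#'   \item{`blocks`}{straight runs: habitat h occupies row h of an
#'     `n_habitats x reps` grid.}
#'   \item{`scattered`}{random cell assignment (for robustness checks).}
#' }
#'
#' @param n_habitats number of habitats.
#' @param reps_per_habitat quadrats per habitat.
#' @param layout `"brick"`, `"blocks"` or `"scattered"`.
#' @param habitats optional habitat names (defaults to the six community
#'   codes when `n_habitats == 6`, else `H1..`).
#' @param seed RNG seed, used by `"scattered"` only.
#' @return a [habitat_lattice()] (without sample ids).
#' @export
lattice_layout <- function(n_habitats, reps_per_habitat,
                           layout = c("brick", "blocks", "scattered"),
                           habitats = NULL, seed = NULL) {
  layout <- match.arg(layout)
  if (is.null(habitats))
    habitats <- if (n_habitats == 6)
      c("QAV", "QSV", "LAG", "PIA", "FOS", "SOH")
    else paste0("H", seq_len(n_habitats))
  if (length(habitats) != n_habitats) stop("need one name per habitat")
  if (layout == "brick") {
    if (reps_per_habitat != 3 || n_habitats %% 2 != 0)
      stop("brick layout needs 3 replicates and an even habitat count; ",
           "use layout = 'blocks'")
    labels <- matrix(NA_character_, n_habitats, 3)
    for (b in seq_len(n_habitats / 2)) {
      r <- 2L * (b - 1L) + 1L
      a <- habitats[2L * b - 1L]; z <- habitats[2L * b]
      labels[r, 1:2] <- a; labels[r + 1L, 1L] <- a
      labels[r, 3L] <- z;  labels[r + 1L, 2:3] <- z
    }
  } else {
    labels <- matrix(rep(habitats, each = reps_per_habitat),
                     n_habitats, reps_per_habitat, byrow = TRUE)
    if (layout == "scattered") {
      if (!is.null(seed)) set.seed(seed)
      labels[] <- sample(labels)
    }
  }
  habitat_lattice(labels)
}

#' Read/write a lattice file
#'
#' Long TSV format: one row per cell with columns `grid_row`, `grid_col`,
#' `habitat` and (optionally) `sample_id`.
#'
#' @param path TSV path.
#' @return a [habitat_lattice()].
#' @export
read_lattice <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  nr <- max(df$grid_row) + 1L
  nc <- max(df$grid_col) + 1L
  labels <- matrix(NA_character_, nr, nc)
  idx <- cbind(df$grid_row + 1L, df$grid_col + 1L)
  labels[idx] <- df$habitat
  samples <- NULL
  if ("sample_id" %in% names(df)) {
    samples <- matrix(NA_character_, nr, nc)
    samples[idx] <- df$sample_id
  }
  habitat_lattice(labels, samples)
}

#' @rdname read_lattice
#' @param lattice a `habitat_lattice`.
#' @export
write_lattice <- function(lattice, path) {
  nr <- nrow(lattice$labels); nc <- ncol(lattice$labels)
  df <- data.frame(grid_row = rep(seq_len(nr) - 1L, nc),
                   grid_col = rep(seq_len(nc) - 1L, each = nr),
                   habitat = as.vector(lattice$labels))
  if (!is.null(lattice$samples)) df$sample_id <- as.vector(lattice$samples)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' All torus translations of a habitat map
#'
#' Generates the exhaustive null family of the torus-translation test: every
#' toroidal shift of each of four map images — identity, 180-degree rotation,
#' horizontal mirror, and mirrored rotation — i.e. `4 * rows * cols` maps,
#' the first of which is the untranslated original. Every map preserves each
#' habitat's cell count exactly.
#'
#' @param lattice a [habitat_lattice()] or a label matrix.
#' @return list of label matrices, identity map first.
#' @export
translations <- function(lattice) {
  lab <- if (inherits(lattice, "habitat_lattice")) lattice$labels
         else as.matrix(lattice)
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr < 2 && nc < 2)
    stop("degenerate 1x1 lattice: no torus translations exist")
  images <- list(lab,
                 lab[rev(seq_len(nr)), rev(seq_len(nc)), drop = FALSE],
                 lab[, rev(seq_len(nc)), drop = FALSE],
                 lab[rev(seq_len(nr)), , drop = FALSE])
  out <- vector("list", 4L * nr * nc)
  k <- 0L
  for (img in images)
    for (dr in 0:(nr - 1L))
      for (dc in 0:(nc - 1L)) {
        k <- k + 1L
        out[[k]] <- img[((seq_len(nr) - 1L + dr) %% nr) + 1L,
                        ((seq_len(nc) - 1L + dc) %% nc) + 1L, drop = FALSE]
      }
  out
}
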