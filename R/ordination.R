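#' Bray-Curtis dissimilarity between samples
#'
#' `d(a, b) = sum_i |x_ia - x_ib| / sum_i (x_ia + x_ib)` on counts; values
#' lie in `[0, 1]`, 0 for identical samples and 1 for samples sharing no
#' OTU. Computed via [vegan::vegdist()].
#'
#' @param x an `otu_table`.
#' @return a `dist` object over samples.
#' @export
bray_curtis <- function(x) {
  zero <- colnames(x$counts)[colSums(x$counts) == 0]
  if (length(zero))
    stop("all-zero sample(s): ", paste(zero, collapse = ", "))
  vegan::vegdist(t(x$counts), method = "bray")
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS of a dissimilarity matrix via [vegan::metaMDS()]
#' with `autotransform = FALSE` (the community transform heuristics of
#' `metaMDS` are deliberately not applied to a precomputed distance matrix);
#' best configuration of `n_restarts` random starts, centred and rotated to
#' principal axes. Deterministic given `seed`.
#'
#' @param d a `dist` (e.g. from [bray_curtis()]).
#' @param k target dimensionality.
#' @param n_restarts random starts.
#' @param seed RNG seed.
#' @return object of class `nmds_result`: list with `coords` (n x k),
#'   `stress` (Kruskal stress-1, 0-1 scale), `converged`, `n_restarts`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, seed = 1) {
  if (any(!is.finite(as.vector(d)))) stop("non-finite distances")
  n <- attr(d, "Size")
  if (is.null(n)) { d <- stats::as.dist(d); n <- attr(d, "Size") }
  if (n < k + 2) stop("need at least k + 2 samples")
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, try = n_restarts, trymax = n_restarts,
                        autotransform = FALSE, wascores = FALSE, trace = 0)
  structure(list(coords = vegan::scores(fit, display = "sites"),
                 stress = fit$stress, converged = isTRUE(fit$converged > 0),
                 n_restarts = n_restarts),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("nmds_result: %d points in %d dims, stress = %.4f\n",
              nrow(x$coords), ncol(x$coords), x$stress))
  invisible(x)
}

#' Habitat-centroid fit on ordination coordinates
#'
#' Fits a grouping factor as centroids on NMDS (or any) coordinates:
#' `R2 = 1 - SS_within / SS_total` over all axes, with a permutation p-value
#' (labels permuted, add-one rule).
#'
#' @param coords numeric matrix (samples x axes).
#' @param groups factor/character of group labels (>= 2 groups, none empty).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `r2`, `p`, `centroids`, `n_perm`.
#' @export
envfit_centroids <- function(coords, groups, n_perm = 999, seed = 1) {
  coords <- as.matrix(coords)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("empty group level")
  ss_tot <- sum(scale(coords, center = TRUE, scale = FALSE)^2)
  r2_of <- function(g) {
    ss_w <- 0
    for (lev in levels(g)) {
      sub <- coords[g == lev, , drop = FALSE]
      ss_w <- ss_w + sum(scale(sub, center = TRUE, scale = FALSE)^2)
    }
    1 - ss_w / ss_tot
  }
  obs <- r2_of(groups)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm))
    if (r2_of(sample(groups)) >= obs - 1e-12) hits <- hits + 1L
  cent <- apply(coords, 2, function(v) tapply(v, groups, mean))
  list(r2 = obs, p = (hits + 1) / (n_perm + 1), centroids = cent,
       n_perm = n_perm)
}

# all permutations of 1..n (n small), as a list
.all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Permutational multivariate analysis of variance
#'
#' Anderson's distance-based one-way PERMANOVA: with `SS_total =
#' sum_{i<j} d_ij^2 / n` and `SS_within` the analogous sum over within-group
#' pairs (each divided by its group size), the statistic is
#' `F = (SS_between / (g - 1)) / (SS_within / (n - g))`. Group labels are
#' permuted freely (single-factor design, no strata); `p` uses the add-one
#' rule. With `permutations = "exact"` all `n!` label permutations are
#' enumerated instead (feasible for small n).
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param groups group labels, one per sample (>= 2 groups).
#' @param permutations number of random permutations, or `"exact"`.
#' @param seed RNG seed (random permutations only).
#' @return object of class `permanova_result`: list with `pseudo_F`, `R2`,
#'   `p`, `n_perm`, `df`.
#' @export
permanova <- function(d, groups, permutations = 999, seed = 1) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  groups <- factor(groups)
  if (length(groups) != n) stop("one group label per sample")
  g <- nlevels(groups)
  if (g < 2) stop("need at least 2 groups")
  ss_total <- sum(D2) / (2 * n)
  ss_within <- function(gr) {
    s <- 0
    for (lev in levels(gr)) {
      idx <- which(gr == lev)
      s <- s + sum(D2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  f_of <- function(gr) {
    ssw <- ss_within(gr)
    ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))
  }
  f_obs <- f_of(groups)
  if (identical(permutations, "exact")) {
    if (n > 9) stop("exact enumeration limited to n <= 9")
    perms <- .all_perms(n)
    ident <- seq_len(n)
    perms <- Filter(function(p) !identical(as.integer(p), ident), perms)
    fs <- vapply(perms, function(p) f_of(groups[p]), numeric(1))
    n_perm <- length(fs)   # n! - 1: the identity is the observed labelling
  } else {
    set.seed(seed)
    n_perm <- permutations
    fs <- vapply(seq_len(n_perm), function(b) f_of(sample(groups)),
                 numeric(1))
  }
  ssw <- ss_within(groups)
  structure(list(pseudo_F = f_obs, R2 = (ss_total - ssw) / ss_total,
                 p = (sum(fs >= f_obs - 1e-12) + 1) / (n_perm + 1),
                 n_perm = n_perm, df = c(between = g - 1, within = n - g)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f (df %d, %d), R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df[1], x$df[2], x$R2, x$p, x$n_perm))
  invisible(x)
}

#' Exact species-accumulation curve
#'
#' Expected richness when `t` of the `T` samples are drawn without
#' replacement, by the closed-form (sample-based rarefaction) estimator
#' `E[S(t)] = sum_i (1 - choose(T - T_i, t) / choose(T, t))` where `T_i` is
#' the number of samples containing OTU i. At `t = T` this is the observed
#' richness; at `t = 1` the mean per-sample richness. The curve is monotone
#' non-decreasing and concave.
#'
#' @param x an `otu_table`.
#' @return data.frame with columns `sites` (t = 1..T) and `richness`.
#' @export
accumulation_curve <- function(x) {
  counts <- x$counts
  n_samp <- ncol(counts)
  t_i <- rowSums(counts > 0)
  richness <- vapply(seq_len(n_samp), function(t)
    sum(1 - exp(lchoose(n_samp - t_i, t) - lchoose(n_samp, t))),
    numeric(1))
  data.frame(sites = seq_len(n_samp), richness = richness)
}
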