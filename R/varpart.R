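#' Redundancy-analysis R-squared of a multivariate response
#'
#' Fits the community matrix on a predictor matrix by multivariate least
#' squares (the regression step of RDA) and returns the proportion of total
#' response variance explained, `r2 = tr(Yhat' Yhat) / tr(Y' Y)` on the
#' column-centred response, together with Ezekiel's adjusted value
#' `adj_r2 = 1 - (1 - r2) (n - 1) / (n - 1 - p)` where `p` is the rank of
#' the centred predictor matrix. Collinear predictor columns are dropped
#' (rank deficiency) with a warning.
#'
#' @param Y numeric response matrix (samples x species).
#' @param X numeric predictor matrix (samples x predictors).
#' @return list with `r2`, `adj_r2` and `rank` (predictors effectively used).
#' @export
rda_r2 <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  if (nrow(X) != n) stop("Y and X must share sample order")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qx <- qr(Xc)
  p <- qx$rank
  if (p < ncol(Xc))
    warning(sprintf("dropping %d collinear predictor column(s)",
                    ncol(Xc) - p))
  if (n <= p + 1)
    stop(sprintf("insufficient residual df: n = %d, rank(X) = %d", n, p))
  ss_tot <- sum(Yc^2)
  if (ss_tot == 0) stop("response has no variance")
  fitted <- qr.fitted(qx, Yc)
  r2 <- sum(fitted^2) / ss_tot
  list(r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 1 - p), rank = p)
}

# forward selection of columns within one predictor set, by adjusted R2;
# stops when no addition improves adj R2 or the budget of columns is reached
.forward_select <- function(Y, X, max_cols) {
  chosen <- integer(0)
  best_adj <- -Inf
  repeat {
    if (length(chosen) >= max_cols || length(chosen) == ncol(X)) break
    cand <- setdiff(seq_len(ncol(X)), chosen)
    adj <- vapply(cand, function(j)
      rda_r2(Y, X[, c(chosen, j), drop = FALSE])$adj_r2, numeric(1))
    if (max(adj) <= best_adj) break
    best_adj <- max(adj)
    chosen <- c(chosen, cand[which.max(adj)])
  }
  X[, sort(chosen), drop = FALSE]
}

#' Three-way variation partitioning by adjusted R-squared
#'
#' Partitions the variation of community composition explained by three
#' predictor sets (canonically topography, soil, light) into the seven
#' fractions of the three-set decomposition plus a residual, by
#' inclusion-exclusion over the adjusted R-squared of the seven non-empty
#' predictor subsets: `a`, `b`, `c` unique to sets 1-3; `d` (1&2), `e`
#' (2&3), `f` (1&3) pairwise-shared; `g` shared by all three;
#' `residual = 1 - adjR2(full)`. The fractions sum to 1 with the residual by
#' construction; shared fractions (and adjusted uniques) may be negative, in
#' which case they are reported but flagged.
#'
#' The community matrix is transformed first (Hellinger by default, the
#' standard pre-transform for abundance RDA; `"chord"` and `"none"` are also
#' available). When the pooled predictor count approaches the sample count
#' (`p >= n - 2`), each set is reduced by forward selection on adjusted
#' R-squared (logged via `message`); disable with `reduce = FALSE`.
#'
#' @param Y community data: an `otu_table` or a samples x species matrix.
#' @param X1,X2,X3 predictor matrices sharing `Y`'s sample order.
#' @param transform `"hellinger"`, `"chord"` or `"none"`.
#' @param reduce allow forward selection when df run short.
#' @param set_names names of the three sets (for reporting).
#' @return object of class `varpart_result`: list with `fractions` (named
#'   a-g + residual), `adj_r2` (the 7 subset values), `totals` (per-set
#'   totals, i.e. each set's own adjusted R2), `negative_fractions`, `n`.
#' @export
varpart3 <- function(Y, X1, X2, X3, transform = c("hellinger", "chord",
                                                  "none"),
                     reduce = TRUE,
                     set_names = c("topography", "soil", "light")) {
  transform <- match.arg(transform)
  if (inherits(Y, "otu_table")) Y <- t(Y$counts)
  Y <- as.matrix(Y)
  Y <- switch(transform,
              hellinger = vegan::decostand(Y, "hellinger"),
              chord = vegan::decostand(Y, "normalize"),
              none = Y)
  X <- list(as.matrix(X1), as.matrix(X2), as.matrix(X3))
  n <- nrow(Y)
  p_all <- sum(vapply(X, ncol, integer(1)))
  if (reduce && p_all >= n - 2) {
    budget <- floor((n - 3) / 3)
    message(sprintf(
      "predictors (%d) approach sample count (%d); forward-selecting <= %d per set",
      p_all, n, budget))
    X <- lapply(X, function(x) .forward_select(Y, x, budget))
  }
  subsets <- list("1" = X[[1]], "2" = X[[2]], "3" = X[[3]],
                  "12" = cbind(X[[1]], X[[2]]),
                  "13" = cbind(X[[1]], X[[3]]),
                  "23" = cbind(X[[2]], X[[3]]),
                  "123" = cbind(X[[1]], X[[2]], X[[3]]))
  adj <- vapply(subsets, function(x)
    suppressWarnings(rda_r2(Y, x)$adj_r2), numeric(1))
  A <- adj[["1"]]; B <- adj[["2"]]; C <- adj[["3"]]
  AB <- adj[["12"]]; AC <- adj[["13"]]; BC <- adj[["23"]]
  ABC <- adj[["123"]]
  g <- A + B + C - AB - AC - BC + ABC
  fr <- c(a = ABC - BC, b = ABC - AC, c = ABC - AB,
          d = A + B - AB - g, e = B + C - BC - g, f = A + C - AC - g,
          g = g, residual = 1 - ABC)
  totals <- stats::setNames(c(A, B, C), set_names)
  structure(list(fractions = fr, adj_r2 = adj, totals = totals,
                 negative_fractions = names(fr)[fr < 0], n = n,
                 transform = transform),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, digits = 4, ...) {
  cat("Variation partitioning (adjusted R2)\n")
  cat("  per-set totals:\n")
  print(round(x$totals, digits))
  cat("  fractions (a-c unique, d-f pairwise shared, g triple shared):\n")
  print(round(x$fractions, digits))
  if (length(x$negative_fractions))
    cat("  negative (not interpretable, conventionally not shown):",
        paste(x$negative_fractions, collapse = ", "), "\n")
  invisible(x)
}

#' Variation partitioning from an environment table
#'
#' Convenience wrapper splitting an [env_table()] into its topography / soil
#' / light groups and calling [varpart3()].
#'
#' @param x an `otu_table`.
#' @param env an `env_table` whose samples match `x`'s.
#' @param ... passed to [varpart3()].
#' @return a `varpart_result`.
#' @export
varpart_env <- function(x, env, ...) {
  grp <- env_groups(env)
  need <- c("topography", "soil", "light")
  miss <- setdiff(need, names(grp))
  if (length(miss))
    stop("environment table lacks group(s): ", paste(miss, collapse = ", "))
  ord <- match(colnames(x$counts), rownames(env$values))
  if (anyNA(ord))
    stop("environment table is missing sample(s): ",
         paste(colnames(x$counts)[is.na(ord)], collapse = ", "))
  varpart3(t(x$counts), grp$topography[ord, , drop = FALSE],
           grp$soil[ord, , drop = FALSE], grp$light[ord, , drop = FALSE],
           ...)
}
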