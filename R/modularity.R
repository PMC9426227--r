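#' Build the weighted community-microbe bipartite network
#'
#' Edge weight (i, h) is the pooled abundance of OTU i in habitat h's
#' samples: raw pooled counts (`"counts"`), per-habitat relative abundance
#' (`"relative"`, the default — each habitat column sums to 1), or presence
#' (`"presence"`). All-zero rows and columns are dropped.
#'
#' @param x a filtered `otu_table`.
#' @param meta sample metadata.
#' @param weight `"relative"`, `"counts"` or `"presence"`.
#' @return object of class `bipartite_network`: list with `weights`
#'   (OTUs x habitats matrix) and `weight` (the scheme used).
#' @export
build_network <- function(x, meta, weight = c("relative", "counts",
                                              "presence")) {
  weight <- match.arg(weight)
  if (nrow(x$counts) == 0) stop("empty OTU table")
  hab <- habitat_of(meta, colnames(x$counts))
  W <- t(rowsum(t(x$counts), hab))                 # otus x habitats
  W <- switch(weight,
              counts = W,
              relative = sweep(W, 2, colSums(W), "/"),
              presence = (W > 0) * 1)
  W <- W[rowSums(W) > 0, colSums(W) > 0, drop = FALSE]
  if (!nrow(W) || !ncol(W)) stop("network has no edges")
  structure(list(weights = W, weight = weight), class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d OTUs x %d habitats (%s weights)\n",
              nrow(x$weights), ncol(x$weights), x$weight))
  invisible(x)
}

#' Barber modularity of a bipartite partition
#'
#' Weighted bipartite modularity
#' `Q = (1/m) * sum_ih (A_ih - k_i d_h / m) * delta(g_i, g_h)` where `m` is
#' the total edge weight, `k_i`/`d_h` the row/column strengths, and the delta
#' restricts the sum to row-column pairs sharing a module. `Q` is 0 for the
#' single-module partition and approaches `1 - 1/k` for `k` equal, perfectly
#' separated modules.
#'
#' @param net a `bipartite_network` or a non-negative weight matrix.
#' @param row_module,col_module integer module labels for rows and columns.
#' @return modularity Q (a single number in `[-1, 1]`).
#' @export
barber_modularity <- function(net, row_module, col_module) {
  W <- if (inherits(net, "bipartite_network")) net$weights else as.matrix(net)
  stopifnot(length(row_module) == nrow(W), length(col_module) == ncol(W))
  m <- sum(W)
  delta <- outer(row_module, col_module, "==")
  sum((W - outer(rowSums(W), colSums(W)) / m) * delta) / m
}

# Q from module bookkeeping: M[mod, h] = summed weights of rows in mod to
# column h; used internally by the optimizer
.q_from_state <- function(W, row_module, col_module, m) {
  mods <- sort(unique(c(row_module, col_module)))
  q <- 0
  k <- rowSums(W); d <- colSums(W)
  for (g in mods) {
    ri <- row_module == g; ci <- col_module == g
    if (any(ri) && any(ci))
      q <- q + sum(W[ri, ci, drop = FALSE]) - sum(k[ri]) * sum(d[ci]) / m
  }
  q / m
}

#' Greedy module search maximising Barber Q
#'
#' Weighted label-propagation initialisation followed by greedy
#' single-node-move hill climbing with module merges, restarted
#' `n_restarts` times from shuffled/random initialisations; the best
#' partition is returned. Deterministic given `seed`. The returned `Q` is
#' exactly [barber_modularity()] of the returned partition and is never below
#' the single-module value of 0. Exactness is only guaranteed at test scale
#' (verified against exhaustive partition enumeration on small networks);
#' on large networks this is a heuristic, as all modularity searches are.
#'
#' @param net a `bipartite_network` or weight matrix.
#' @param n_restarts number of random restarts.
#' @param seed RNG seed.
#' @return object of class `module_partition`: list with `row_module`,
#'   `col_module` (named, contiguous integers from 1), `n_modules` and `Q`.
#' @export
optimize_modules <- function(net, n_restarts = 20, seed = 1) {
  W <- if (inherits(net, "bipartite_network")) net$weights else as.matrix(net)
  if (!nrow(W) || !ncol(W) || sum(W) == 0) stop("network is empty")
  set.seed(seed)
  nr <- nrow(W); nc <- ncol(W)
  m <- sum(W); k <- rowSums(W); d <- colSums(W)
  best <- NULL

  for (r in seq_len(n_restarts)) {
    if (r == 1) {                       # label propagation from column seeds
      cm <- seq_len(nc)
      rm <- apply(W, 1, which.max)
    } else {                            # random initial labels
      n_init <- sample.int(nr + nc, 1)
      rm <- sample.int(n_init, nr, replace = TRUE)
      cm <- sample.int(n_init, nc, replace = TRUE)
    }
    repeat {
      improved <- FALSE
      # single-node moves, random order over rows and columns
      for (node in sample.int(nr + nc)) {
        if (node <= nr) {
          i <- node
          w_to <- rowsum(W[i, ], cm)               # weight to each col-module
          mods <- sort(unique(c(rm, cm)))
          dcol <- vapply(mods, function(g) sum(d[cm == g]), numeric(1))
          wvec <- numeric(length(mods))
          wvec[match(rownames(w_to), as.character(mods))] <- w_to[, 1]
          gain <- (wvec - k[i] * dcol / m) / m     # Q share of row i by module
          fresh <- max(mods) + 1L
          cand <- c(mods, fresh); gains <- c(gain, 0)
          cur <- gains[match(rm[i], cand)]
          pick <- which.max(gains)
          if (gains[pick] > cur + 1e-12) {
            rm[i] <- cand[pick]; improved <- TRUE
          }
        } else {
          h <- node - nr
          w_to <- rowsum(W[, h], rm)
          mods <- sort(unique(c(rm, cm)))
          krow <- vapply(mods, function(g) sum(k[rm == g]), numeric(1))
          wvec <- numeric(length(mods))
          wvec[match(rownames(w_to), as.character(mods))] <- w_to[, 1]
          gain <- (wvec - d[h] * krow / m) / m
          fresh <- max(mods) + 1L
          cand <- c(mods, fresh); gains <- c(gain, 0)
          cur <- gains[match(cm[h], cand)]
          pick <- which.max(gains)
          if (gains[pick] > cur + 1e-12) {
            cm[h] <- cand[pick]; improved <- TRUE
          }
        }
      }
      # pairwise module merges
      mods <- sort(unique(c(rm, cm)))
      if (length(mods) > 1) {
        for (a_i in seq_along(mods)) for (b_i in seq_along(mods)) {
          if (a_i >= b_i) next
          a <- mods[a_i]; b <- mods[b_i]
          ra <- rm == a; rb <- rm == b; ca <- cm == a; cb <- cm == b
          dq <- (sum(W[ra, cb, drop = FALSE]) + sum(W[rb, ca, drop = FALSE]) -
                 (sum(k[ra]) * sum(d[cb]) + sum(k[rb]) * sum(d[ca])) / m) / m
          if (dq > 1e-12) {
            rm[rb] <- a; cm[cb] <- a
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    q <- .q_from_state(W, rm, cm, m)
    if (is.null(best) || q > best$q + 1e-12)
      best <- list(q = q, rm = rm, cm = cm)
  }

  if (best$q < 0) {                     # never worse than one module (Q = 0)
    best <- list(q = 0, rm = rep(1L, nr), cm = rep(1L, nc))
  }
  relab <- match(c(best$rm, best$cm), sort(unique(c(best$rm, best$cm))))
  rm <- stats::setNames(relab[seq_len(nr)], rownames(W))
  cm <- stats::setNames(relab[nr + seq_len(nc)], colnames(W))
  structure(list(row_module = rm, col_module = cm,
                 n_modules = length(unique(relab)),
                 Q = barber_modularity(W, rm, cm)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules, Q = %.4f\n", x$n_modules, x$Q))
  invisible(x)
}

#' Export a bipartite network as an edge list
#'
#' @param net a `bipartite_network`.
#' @param path TSV output path (columns otu_id, habitat, weight).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  W <- net$weights
  idx <- which(W > 0, arr.ind = TRUE)
  df <- data.frame(otu_id = rownames(W)[idx[, 1]],
                   habitat = colnames(W)[idx[, 2]],
                   weight = W[idx])
  df <- df[order(df$otu_id, df$habitat), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
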