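# Independent brute-force oracles and fixture builders. Everything here is
# written against the definitions directly (nested loops, enumeration), never
# by calling the implementation under test.

make_table <- function(counts, ids = NULL, samples = NULL, taxonomy = NULL) {
  counts <- as.matrix(counts)
  rownames(counts) <- ids %||% paste0("OTU", seq_len(nrow(counts)))
  colnames(counts) <- samples %||% paste0("s", seq_len(ncol(counts)))
  otu_table(counts, taxonomy = taxonomy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- torus translations -----------------------------------------------------

# every toroidal shift of the 4 images, by literal nested loops
oracle_translations <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  imgs <- list(lab, NULL, NULL, NULL)
  rot <- mir <- flp <- lab
  for (i in 1:nr) for (j in 1:nc) {
    rot[i, j] <- lab[nr - i + 1, nc - j + 1]
    mir[i, j] <- lab[i, nc - j + 1]
    flp[i, j] <- lab[nr - i + 1, j]
  }
  imgs[[2]] <- rot; imgs[[3]] <- mir; imgs[[4]] <- flp
  out <- list()
  for (img in imgs) for (dr in 0:(nr - 1)) for (dc in 0:(nc - 1)) {
    m <- img
    for (i in 1:nr) for (j in 1:nc)
      m[i, j] <- img[(i - 1 + dr) %% nr + 1, (j - 1 + dc) %% nc + 1]
    out[[length(out) + 1]] <- m
  }
  out
}

# torus-test p-values for one OTU x habitat by exhaustive hand enumeration
oracle_torus_p <- function(rel_by_cell, lab, habitat) {
  maps <- oracle_translations(lab)
  stats <- vapply(maps, function(m)
    mean(rel_by_cell[as.vector(m) == habitat]), numeric(1))
  obs <- stats[1]; null <- stats[-1]
  list(obs = obs,
       p_pos = (sum(null >= obs - 1e-12) + 1) / (length(null) + 1),
       p_neg = (sum(null <= obs + 1e-12) + 1) / (length(null) + 1))
}

# --- bipartite modularity ---------------------------------------------------

# Barber Q by literal double loop over every (row, col) pair
oracle_barber <- function(W, gr, gc) {
  m <- sum(W); k <- rowSums(W); d <- colSums(W)
  q <- 0
  for (i in seq_len(nrow(W))) for (h in seq_len(ncol(W)))
    if (gr[i] == gc[h]) q <- q + W[i, h] - k[i] * d[h] / m
  q / m
}

# all set partitions of n elements as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(a, mx) {
    if (length(a) == n) { out[[length(out) + 1L]] <<- a; return() }
    for (v in seq_len(mx + 1L)) rec(c(a, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# global optimum of Barber Q by exhaustive sweep over set partitions
oracle_best_q <- function(W) {
  nr <- nrow(W)
  m <- sum(W); k <- rowSums(W); d <- colSums(W)
  E <- W - outer(k, d) / m
  best <- -Inf
  for (p in all_partitions(nr + ncol(W))) {
    delta <- outer(p[seq_len(nr)], p[nr + seq_len(ncol(W))], "==")
    q <- sum(E[delta]) / m
    if (q > best) best <- q
  }
  best
}

# --- ordination -------------------------------------------------------------

# expected richness at t samples, averaged over every subset of size t
oracle_accumulation <- function(counts, t) {
  subsets <- utils::combn(ncol(counts), t)
  mean(apply(subsets, 2, function(cols)
    sum(rowSums(counts[, cols, drop = FALSE]) > 0)))
}

# matrix of all n! permutations of 1..n, one per row
gtools_style_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_style_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# PERMANOVA pseudo-F by direct loop over pairs
oracle_permanova_F <- function(D, groups) {
  n <- nrow(D); levs <- unique(groups); g <- length(levs)
  sst <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) sst <- sst + D[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (lev in levs) {
    idx <- which(groups == lev)
    if (length(idx) > 1)
      for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx))
        ssw <- ssw + D[idx[a], idx[b]]^2 / length(idx)
  }
  ((sst - ssw) / (g - 1)) / (ssw / (n - g))
}
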