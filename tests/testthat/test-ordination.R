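test_that("Bray-Curtis matches hand computation and its bounds", {
  x <- make_table(cbind(c(1, 2), c(2, 1)))
  d <- bray_curtis(x)
  expect_equal(as.vector(d), 1 / 3)    # (|1-2| + |2-1|) / (1+2+2+1)

  ident <- make_table(cbind(c(3, 5), c(3, 5)))
  expect_equal(as.vector(bray_curtis(ident)), 0)
  disjoint <- make_table(cbind(c(4, 0), c(0, 9)))
  expect_equal(as.vector(bray_curtis(disjoint)), 1)

  set.seed(2)
  r <- make_table(matrix(rpois(60, 5), 10, 6))
  D <- as.matrix(bray_curtis(r))
  # definition, looped
  for (a in 1:5) for (b in (a + 1):6) {
    xa <- r$counts[, a]; xb <- r$counts[, b]
    expect_equal(D[a, b], sum(abs(xa - xb)) / sum(xa + xb))
  }
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
})

test_that("NMDS reaches near-zero stress on exactly embeddable distances", {
  set.seed(4)
  pts <- matrix(rnorm(16), 8, 2)
  d <- dist(pts)
  fit <- suppressWarnings(nmds(d, k = 2, n_restarts = 10, seed = 1))
  expect_lt(fit$stress, 0.01)
  expect_equal(dim(fit$coords), c(8, 2))

  # same matrix, same seed: deterministic
  fit2 <- suppressWarnings(nmds(d, k = 2, n_restarts = 10, seed = 1))
  expect_equal(fit2$coords, fit$coords)
  expect_error(nmds(dist(pts[1:3, ]), k = 2), "k \\+ 2")
})

test_that("centroid fits recover exact group separation statistics", {
  coords <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  g <- rep(c("a", "b"), each = 3)
  fit <- envfit_centroids(coords, g, n_perm = 99, seed = 1)
  expect_equal(fit$r2, 1)              # zero within-group variance

  same <- matrix(rnorm(12), 6, 2)
  expect_error(envfit_centroids(same, rep("a", 6)), "2 groups")
  # identical group centroids (both at the origin): R2 = 0
  mirrored <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  fitm <- envfit_centroids(mirrored, c("a", "b", "a", "b"), n_perm = 9,
                           seed = 1)
  expect_equal(fitm$r2, 0)

  # hand-computed sums of squares on a small labelled set
  set.seed(7)
  cc <- matrix(rnorm(12), 6, 2)
  gl <- c("a", "a", "b", "b", "c", "c")
  ssw <- 0
  for (lev in unique(gl)) {
    sub <- cc[gl == lev, , drop = FALSE]
    ssw <- ssw + sum(sweep(sub, 2, colMeans(sub))^2)
  }
  sst <- sum(sweep(cc, 2, colMeans(cc))^2)
  fit3 <- envfit_centroids(cc, gl, n_perm = 199, seed = 5)
  expect_equal(fit3$r2, 1 - ssw / sst)
  # cross-check against vegan::envfit on the same configuration
  vf <- vegan::envfit(cc, data.frame(g = factor(gl)), permutations = 0)
  expect_equal(unname(fit3$r2), unname(vf$factors$r), tolerance = 1e-10)
})

test_that("PERMANOVA matches its definition, vegan, and exact enumeration", {
  set.seed(15)
  x <- make_table(matrix(rpois(8 * 20, 6), 20, 8))
  d <- bray_curtis(x)
  g <- rep(c("u", "v"), each = 4)
  res <- permanova(d, g, permutations = 299, seed = 2)
  expect_equal(res$pseudo_F, oracle_permanova_F(as.matrix(d), g))
  expect_true(res$R2 >= 0 && res$R2 <= 1)

  av <- vegan::adonis2(d ~ g, permutations = 299)
  expect_equal(res$pseudo_F, av$F[1])
  expect_equal(res$R2, av$R2[1])

  # exhaustive enumeration at n = 6 equals an independent oracle loop
  x6 <- make_table(matrix(rpois(6 * 15, 5), 15, 6))
  d6 <- bray_curtis(x6)
  g6 <- rep(c("u", "v"), each = 3)
  ex <- permanova(d6, g6, permutations = "exact")
  expect_equal(ex$n_perm, factorial(6) - 1)
  D6 <- as.matrix(d6)
  f_obs <- oracle_permanova_F(D6, g6)
  perms <- asplit(gtools_style_perms(6), 1)
  fs <- vapply(perms, function(p) oracle_permanova_F(D6, g6[p]), numeric(1))
  n_ge <- sum(fs >= f_obs - 1e-12)     # includes the identity labelling
  expect_equal(ex$p, n_ge / factorial(6))

  # extreme separation at full enumeration: minimal attainable p. Label
  # permutations that preserve the two blocks (3! * 3! * 2 = 72 of the 720)
  # reproduce the observed F exactly, so the floor is 0.1 at n = 6
  D <- matrix(1, 6, 6) - diag(6)
  D[1:3, 1:3] <- 0.01; D[4:6, 4:6] <- 0.01; diag(D) <- 0
  exs <- permanova(as.dist(D), g6, permutations = "exact")
  expect_equal(exs$p, 72 / 720)
  expect_error(permanova(d6, rep("u", 6)), "2 groups")
})

test_that("PERMANOVA F is near 1 and p near-uniform on structureless data", {
  set.seed(44)
  fs <- ps <- numeric(30)
  for (i in 1:30) {
    D <- as.matrix(dist(matrix(rnorm(8 * 3), 8)))
    g <- sample(rep(c("u", "v"), each = 4))
    r <- permanova(as.dist(D), g, permutations = 99, seed = i)
    fs[i] <- r$pseudo_F; ps[i] <- r$p
  }
  expect_gt(mean(fs), 0.6); expect_lt(mean(fs), 1.6)
  expect_gt(mean(ps), 0.3)             # not systematically significant
})

test_that("accumulation curve equals the subset-enumeration oracle", {
  set.seed(10)
  x <- make_table(matrix(rpois(12 * 5, 0.8), 12, 5))
  x$counts[1, ] <- x$counts[1, ] + 1   # keep all samples nonzero
  curve <- accumulation_curve(x)
  for (t in 1:5)
    expect_equal(curve$richness[t], oracle_accumulation(x$counts, t))
  # endpoints: observed richness at t = T, mean per-sample richness at t = 1
  expect_equal(curve$richness[5], sum(rowSums(x$counts) > 0))
  expect_equal(curve$richness[1], mean(colSums(x$counts > 0)))
  # monotone and concave
  expect_true(all(diff(curve$richness) >= -1e-12))
  expect_true(all(diff(diff(curve$richness)) <= 1e-12))
  # agrees with vegan's exact method
  sp <- suppressWarnings(vegan::specaccum(t(x$counts), method = "exact"))
  expect_equal(curve$richness, as.vector(sp$richness))
})
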