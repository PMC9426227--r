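test_that("translations enumerate 4*rows*cols maps preserving habitat areas", {
  lab <- matrix(c("A", "A", "B", "B"), 2, 2)
  maps <- translations(lab)
  expect_length(maps, 16)
  expect_identical(maps[[1]], lab)
  base <- sort(as.vector(lab))
  for (m in maps) expect_identical(sort(as.vector(m)), base)

  # one uniform label: every map identical
  uni <- matrix("A", 2, 3)
  expect_true(all(vapply(translations(uni), identical, logical(1), uni)))

  expect_error(translations(matrix("A", 1, 1)), "1x1")
})

test_that("translations match an independent nested-loop enumeration", {
  set.seed(8)
  lab <- matrix(sample(c("A", "B"), 12, replace = TRUE), 3, 4)
  got <- translations(lab)
  want <- oracle_translations(lab)
  expect_length(got, length(want))
  key <- function(m) paste(as.vector(m), collapse = "")
  expect_setequal(vapply(got, key, character(1)),
                  vapply(want, key, character(1)))
  # multiset equality, not just set equality
  expect_identical(sort(table(vapply(got, key, character(1)))),
                   sort(table(vapply(want, key, character(1)))))
})

test_that("habitat_stat averages depth-normalised abundance over habitat cells", {
  lab <- matrix(c("A", "A", "B", "B", "C", "C"), 2, 3)
  row <- c(2, 4, 6, 8, 10, 12)
  depths <- c(10, 20, 10, 20, 10, 20)
  # hand loop
  for (h in c("A", "B", "C")) {
    cells <- which(as.vector(lab) == h)
    expect_equal(habitat_stat(row, lab, h, depths),
                 mean(row[cells] / depths[cells]))
  }
  # uniform relative abundance: identical statistic everywhere
  expect_equal(habitat_stat(depths / 2, lab, "A", depths),
               habitat_stat(depths / 2, lab, "C", depths))
  expect_error(habitat_stat(row, lab, "Z", depths), "absent")
})

test_that("torus test p-values equal exhaustive enumeration on small lattices", {
  for (seed in 1:3) {
    sc <- synthetic_scenario(n_otus = 12, specialist_fraction = 0.5,
                             fold_enrichment = 5, depth = 2000, seed = seed)
    sim <- generate_community(sc)
    res <- torus_test(sim$otu, sim$meta)
    lab <- sim$lattice$labels
    cell_samples <- as.vector(sim$lattice$samples)
    depths <- colSums(sim$otu$counts)[cell_samples]
    for (otu in sample(rownames(sim$otu$counts), 4)) {
      rel <- sim$otu$counts[otu, cell_samples] / depths
      for (h in c("QAV", "SOH")) {
        o <- oracle_torus_p(rel, lab, h)
        row <- res[res$otu_id == otu & res$habitat == h, ]
        expect_equal(row$observed, o$obs)
        expect_equal(row$p_pos, o$p_pos)
        expect_equal(row$p_neg, o$p_neg)
      }
    }
  }
})

test_that("a perfectly concentrated OTU attains the minimal attainable p", {
  # 6-habitat block lattice; an OTU with all reads in one habitat's cells and
  # equal cell depth: p_pos = (#null maps putting all three cells on the
  # high-count cells + 1) / 72, found here by exhaustive enumeration
  lat <- lattice_layout(6, 3, layout = "brick")
  hab <- "LAG"
  cells <- which(as.vector(lat$labels) == hab)
  counts <- matrix(1, 2, 18)
  counts[1, cells] <- 100
  counts[2, ] <- 500 - colSums(counts[1, , drop = FALSE])  # equal depth
  meta <- data.frame(sample_id = paste0("s", 1:18),
                     habitat = as.vector(lat$labels),
                     grid_row = rep(0:5, times = 3),
                     grid_col = rep(0:2, each = 6),
                     replicate = 1)
  x <- make_table(counts, ids = c("conc", "fill"),
                  samples = meta$sample_id)
  res <- torus_test(x, meta, alpha = 0.05)
  rel <- counts[1, ] / 500
  o <- oracle_torus_p(rel, lat$labels, hab)
  row <- res[res$otu_id == "conc" & res$habitat == hab, ]
  expect_equal(row$p_pos, o$p_pos)
  # the brick patches have no torus symmetry, so only the identity map
  # reproduces the concentrated configuration: p = 1/72
  expect_equal(row$p_pos, 1 / 72)
  expect_identical(row$classification, "positive")

  # straight-run patches ARE reproduced by the mirrored/rotated images:
  # the same construction on a "blocks" layout cannot reach p <= 3/72
  lat2 <- lattice_layout(6, 3, layout = "blocks")
  cells2 <- which(as.vector(lat2$labels) == hab)
  counts2 <- matrix(1, 2, 18)
  counts2[1, cells2] <- 100
  counts2[2, ] <- 500 - colSums(counts2[1, , drop = FALSE])
  meta2 <- data.frame(sample_id = paste0("s", 1:18),
                      habitat = as.vector(lat2$labels),
                      grid_row = rep(0:5, times = 3),
                      grid_col = rep(0:2, each = 6),
                      replicate = 1)
  x2 <- make_table(counts2, ids = c("conc", "fill"),
                   samples = meta2$sample_id)
  res2 <- torus_test(x2, meta2)
  row2 <- res2[res2$otu_id == "conc" & res2$habitat == hab, ]
  expect_gte(row2$p_pos, 4 / 72)
})

test_that("ties and the add-one rule keep p-values in (0, 1] and honest", {
  sim <- generate_community(synthetic_scenario(n_otus = 30, depth = 1000,
                                               seed = 13))
  res <- torus_test(sim$otu, sim$meta)
  expect_true(all(res$p_pos > 0 & res$p_pos <= 1))
  expect_true(all(res$p_neg > 0 & res$p_neg <= 1))
  expect_true(all(res$p_pos + res$p_neg > 1))

  # an OTU with equal counts in all cells ties every translation: neutral
  flat <- make_table(rbind(rep(7, 18), rep(3, 18)),
                     samples = sim$meta$sample_id)
  resf <- torus_test(flat, sim$meta)
  expect_true(all(resf$p_pos == 1 & resf$p_neg == 1))
  expect_true(all(resf$classification == "neutral"))

  expect_error(torus_test(sim$otu, sim$meta, alpha = 0.6), "alpha")
  expect_error(torus_test(sim$otu, sim$meta, alpha = 0), "alpha")
})

test_that("classification is invariant to OTU relabeling and lattice rotation", {
  sim <- generate_community(synthetic_scenario(n_otus = 25, depth = 3000,
                                               fold_enrichment = 6,
                                               seed = 17))
  res <- torus_test(sim$otu, sim$meta)

  # relabel OTUs
  x2 <- otu_table(sim$otu$counts[nrow(sim$otu$counts):1, ])
  res2 <- torus_test(x2, sim$meta)
  key <- function(r) r[order(r$otu_id, r$habitat),
                       c("otu_id", "habitat", "classification")]
  expect_equal(key(res2), key(res), ignore_attr = TRUE)

  # rotate lattice and coordinates together (torus shift by one row/col)
  meta3 <- sim$meta
  nr <- max(meta3$grid_row) + 1; nc <- max(meta3$grid_col) + 1
  meta3$grid_row <- (meta3$grid_row + 1) %% nr
  meta3$grid_col <- (meta3$grid_col + 2) %% nc
  res3 <- torus_test(sim$otu, meta3)
  expect_equal(key(res3), key(res), ignore_attr = TRUE)
})

test_that("specialist calls aggregate per OTU with best-habitat assignment", {
  res <- data.frame(
    otu_id = rep(c("a", "b"), each = 3),
    habitat = rep(c("H1", "H2", "H3"), 2),
    observed = c(5, 1, 4, 1, 1, 1),
    p_pos = c(1 / 72, 0.5, 2 / 72, 0.4, 0.9, 0.2),
    p_neg = 1,
    classification = c("positive", "neutral", "positive",
                       "neutral", "neutral", "neutral"))
  sp <- specialists(res)
  expect_identical(sp$specialist, c(TRUE, FALSE))
  expect_identical(sp$best_habitat[1], "H1")
  expect_identical(sp$positive_habitats[1], "H1,H3")
  expect_true(is.na(sp$best_habitat[2]))
})

test_that("association summaries reproduce count-to-percentage arithmetic", {
  # 10 OTUs x 2 habitats; 3 positive (one for both habitats), 1 negative
  cls <- rep("neutral", 20)
  df <- data.frame(otu_id = rep(paste0("o", 1:10), 2),
                   habitat = rep(c("X", "Y"), each = 10),
                   classification = cls)
  df$classification[df$otu_id %in% c("o1", "o2") & df$habitat == "X"] <- "positive"
  df$classification[df$otu_id %in% c("o2", "o3") & df$habitat == "Y"] <- "positive"
  df$classification[df$otu_id == "o4" & df$habitat == "X"] <- "negative"
  s <- summarize_associations(df)
  expect_equal(s$overall$n_tested, 10)
  expect_equal(s$overall$n_positive, 3)
  expect_equal(s$overall$pct_positive, 30)
  expect_equal(s$overall$pct_neutral, 60)  # o4 is negative, not neutral
  ph <- s$per_habitat
  expect_equal(ph$pct_positive[ph$habitat == "X"], 20)
  expect_equal(ph$pct_positive[ph$habitat == "Y"], 20)

  # all-neutral input: 0% positive, 100% neutral
  df0 <- data.frame(otu_id = rep(paste0("o", 1:5), 2),
                    habitat = rep(c("X", "Y"), each = 5),
                    classification = "neutral")
  s0 <- summarize_associations(df0)
  expect_equal(s0$overall$pct_positive, 0)
  expect_equal(s0$overall$pct_neutral, 100)

  # forest-type pooling counts each OTU once per forest type
  s2 <- summarize_associations(df, forest_type_map = c(X = "conif",
                                                       Y = "conif"))
  expect_equal(s2$forest_types$n_otus, 3)
  expect_equal(s2$forest_types$pct, 30)
})
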