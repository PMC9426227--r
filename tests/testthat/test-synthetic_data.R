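test_that("generation is deterministic and respects the multinomial depth", {
  sc <- synthetic_scenario(n_otus = 60, depth = 3000, seed = 9)
  a <- generate_community(sc)
  b <- generate_community(sc)
  expect_identical(a$otu$counts, b$otu$counts)
  expect_identical(a$env$values, b$env$values)
  expect_identical(a$truth, b$truth)

  expect_true(all(colSums(a$otu$counts) == 3000))
  expect_equal(nrow(a$meta), 18)
  expect_equal(sort(unique(a$meta$habitat)),
               sort(unique(as.vector(a$lattice$labels))))
  # truth table covers every OTU; specialists carry a preferred habitat
  expect_identical(a$truth$otu_id, rownames(a$otu$counts))
  expect_true(all(!is.na(a$truth$preferred_habitat[a$truth$specialist])))
  expect_true(all(is.na(a$truth$preferred_habitat[!a$truth$specialist])))
})

test_that("null_scenario strips the planted structure and nothing else", {
  sc <- synthetic_scenario(specialist_fraction = 0.4, seed = 5)
  ns <- null_scenario(sc)
  expect_equal(ns$specialist_fraction, 0)
  ns$specialist_fraction <- sc$specialist_fraction
  expect_identical(ns, sc)

  sim <- generate_community(null_scenario(synthetic_scenario(n_otus = 40,
                                                             depth = 400,
                                                             seed = 1)))
  expect_equal(sum(sim$truth$specialist), 0)
})

test_that("observed specialist proportions match the multinomial expectation", {
  sc <- synthetic_scenario(n_otus = 40, specialist_fraction = 0.5,
                           fold_enrichment = 6, depth = 4000, seed = 21)
  sim <- generate_community(sc)
  spec_id <- sim$truth$otu_id[sim$truth$specialist][1]
  pref <- sim$truth$preferred_habitat[sim$truth$otu_id == spec_id]
  pref_sample <- sim$meta$sample_id[sim$meta$habitat == pref][1]

  # expected composition in a preferred-habitat sample, reconstructed from
  # the truth table and the scenario parameters (not from the counts)
  set.seed(sc$seed)
  a <- rlnorm(sc$n_otus, sc$abundance_logmean, sc$abundance_logsd)
  names(a) <- sim$truth$otu_id
  e <- a
  boost <- sim$truth$specialist & sim$truth$preferred_habitat == pref
  e[boost] <- e[boost] * sc$fold_enrichment
  p_expect <- unname(e[spec_id] / sum(e))

  # Monte-Carlo from the fixed composition vs the analytic expectation
  set.seed(77)
  props <- rmultinom(200, sc$depth, e)[spec_id, ] / sc$depth
  se <- sqrt(p_expect * (1 - p_expect) / sc$depth / 200)
  expect_lt(abs(mean(props) - p_expect), 3 * se)
  # and the generated sample itself is consistent with that composition
  obs <- sim$otu$counts[spec_id, pref_sample] / sc$depth
  expect_lt(abs(obs - p_expect),
            5 * sqrt(p_expect * (1 - p_expect) / sc$depth))
})

test_that("env_effect = 0 leaves no habitat signal in the environment", {
  fs <- unlist(lapply(1:4, function(s) {
    sim <- generate_community(synthetic_scenario(n_otus = 5, depth = 50,
                                                 env_effect = 0, seed = s))
    apply(sim$env$values, 2, function(v)
      summary(aov(v ~ factor(sim$meta$habitat)))[[1]]$`F value`[1])
  }))
  # F(5, 12) has mean 1.2 under the null; the average over 60 draws should
  # sit near it
  expect_gt(mean(fs), 0.6)
  expect_lt(mean(fs), 2.0)

  sim <- generate_community(synthetic_scenario(n_otus = 5, depth = 50,
                                               env_effect = 5, seed = 1))
  f_sig <- apply(sim$env$values, 2, function(v)
    summary(aov(v ~ factor(sim$meta$habitat)))[[1]]$`F value`[1])
  expect_gt(mean(f_sig), 5)
})

test_that("written community files read back to the same objects", {
  sim <- generate_community(synthetic_scenario(n_otus = 25, depth = 600,
                                               seed = 4))
  dir <- withr::local_tempdir()
  write_community(sim, dir)
  expect_identical(read_otu_table(file.path(dir, "otu.tsv"))$counts,
                   sim$otu$counts)
  expect_identical(read_sample_metadata(file.path(dir, "meta.tsv")),
                   sim$meta)
  lat <- read_lattice(file.path(dir, "lattice.tsv"))
  expect_identical(lat$labels, sim$lattice$labels)
  expect_identical(lat$samples, sim$lattice$samples)
  tr <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(sum(tr$specialist), sum(sim$truth$specialist))
})

test_that("scenario validation rejects impossible settings", {
  expect_error(synthetic_scenario(specialist_fraction = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_scenario(fold_enrichment = 0.5))
  expect_error(lattice_layout(5, 3, "brick"), "even habitat count")
})
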