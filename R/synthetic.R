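#' Define a synthetic community scenario
#'
#' The generator emulates the study design the pipeline targets: H habitat
#' (plant community) types with a fixed number of replicate quadrats laid out
#' on a rectangular lattice, lognormal OTU base abundances, a configurable
#' fraction of habitat specialists enriched by a fold factor in one preferred
#' habitat, and fixed-depth multinomial sequencing of each sample. Defaults
#' follow the 6-habitat x 3-quadrat design with 500 OTUs at 20,000 reads per
#' sample.
#'
#' @param n_habitats number of habitat types.
#' @param reps_per_habitat replicate quadrats per habitat.
#' @param n_otus number of OTUs.
#' @param specialist_fraction fraction of OTUs that are habitat specialists,
#'   in `[0, 1]`.
#' @param fold_enrichment expected-abundance multiplier (>= 1) of a
#'   specialist in its preferred habitat; 1 makes specialists
#'   indistinguishable from neutral OTUs.
#' @param abundance_logmean,abundance_logsd parameters of the lognormal base
#'   abundance distribution (log scale).
#' @param depth reads per sample (fixed; sampling is multinomial).
#' @param env_effect strength of the habitat signal in the environment
#'   variables (0 = no signal; variables are habitat means scaled by this
#'   factor plus unit Gaussian noise).
#' @param layout lattice layout, see [lattice_layout()].
#' @param seed integer RNG seed; generation is reproducible given the seed.
#' @return object of class `synthetic_scenario` (a validated list).
#' @export
synthetic_scenario <- function(n_habitats = 6, reps_per_habitat = 3,
                               n_otus = 500, specialist_fraction = 0.33,
                               fold_enrichment = 8, abundance_logmean = 0,
                               abundance_logsd = 1, depth = 20000,
                               env_effect = 1,
                               layout = c("brick", "blocks", "scattered"),
                               seed = 1) {
  layout <- match.arg(layout)
  stopifnot(n_habitats >= 2, reps_per_habitat >= 1, n_otus >= 1,
            depth > 0, fold_enrichment >= 1, abundance_logsd >= 0,
            env_effect >= 0)
  if (specialist_fraction < 0 || specialist_fraction > 1)
    stop("specialist_fraction must be in [0, 1]")
  structure(list(n_habitats = n_habitats,
                 reps_per_habitat = reps_per_habitat, n_otus = n_otus,
                 specialist_fraction = specialist_fraction,
                 fold_enrichment = fold_enrichment,
                 abundance_logmean = abundance_logmean,
                 abundance_logsd = abundance_logsd, depth = as.integer(depth),
                 env_effect = env_effect, layout = layout,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Habitat-free copy of a scenario
#'
#' Returns the scenario with `specialist_fraction = 0` and everything else
#' unchanged — the null used for type-I-error studies of the torus test.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a `synthetic_scenario`.
#' @export
null_scenario <- function(scenario) {
  scenario$specialist_fraction <- 0
  scenario
}

# environment variable names of the three groups
.env_vars <- c(elevation = "topography", slope = "topography",
               aspect = "topography", convexity = "topography",
               pH = "soil", SWC = "soil", N = "soil", P = "soil",
               SOM = "soil",
               LT = "light", SR = "light", TR = "light", CC = "light",
               ALA = "light", LAI = "light")

#' Generate a synthetic community with known planted structure
#'
#' Draws base abundances `a_i ~ lognormal`, assigns each specialist OTU one
#' preferred habitat uniformly at random, sets its expected abundance to
#' `fold_enrichment * a_i` there (and `a_i` elsewhere), and draws each
#' sample's counts from a multinomial at the configured depth over the
#' sample's expected composition — so column sums equal `depth` exactly.
#' Habitat labels tile the lattice per the scenario's layout; environment
#' variables are habitat-specific means scaled by `env_effect` plus unit
#' Gaussian noise, tagged into the topography/soil/light groups. The truth
#' table records each OTU's specialist status and preferred habitat so that
#' recovery metrics are computed by joins, not by re-simulation.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list of class `synthetic_community` with elements `otu`
#'   ([otu_table()]), `meta`, `lattice`, `env` ([env_table()]), `truth`
#'   (data.frame `otu_id`, `specialist`, `preferred_habitat`), and
#'   `scenario`.
#' @export
generate_community <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  sc <- scenario
  lattice <- lattice_layout(sc$n_habitats, sc$reps_per_habitat, sc$layout)
  habitats <- sort(unique(as.vector(lattice$labels)))
  n_samples <- sc$n_habitats * sc$reps_per_habitat

  # metadata: cells in row-major order, replicate numbering within habitat
  nr <- nrow(lattice$labels); nc <- ncol(lattice$labels)
  cell_hab <- as.vector(t(lattice$labels))            # row-major
  rep_idx <- stats::ave(seq_along(cell_hab), cell_hab, FUN = seq_along)
  sample_ids <- sprintf("%s_%d", cell_hab, rep_idx)
  meta <- sample_metadata(data.frame(
    sample_id = sample_ids, habitat = cell_hab,
    grid_row = rep(seq_len(nr) - 1L, each = nc),
    grid_col = rep(seq_len(nc) - 1L, times = nr),
    replicate = rep_idx, stringsAsFactors = FALSE))
  samples <- matrix(NA_character_, nr, nc)
  samples[cbind(meta$grid_row + 1L, meta$grid_col + 1L)] <- meta$sample_id
  lattice$samples <- samples

  otu_ids <- sprintf("OTU%04d", seq_len(sc$n_otus))
  a <- stats::rlnorm(sc$n_otus, sc$abundance_logmean, sc$abundance_logsd)
  n_spec <- round(sc$specialist_fraction * sc$n_otus)
  spec <- rep(FALSE, sc$n_otus)
  spec[sample.int(sc$n_otus, n_spec)] <- TRUE
  pref <- rep(NA_character_, sc$n_otus)
  pref[spec] <- sample(habitats, n_spec, replace = TRUE)

  expected <- matrix(a, sc$n_otus, n_samples,
                     dimnames = list(otu_ids, meta$sample_id))
  for (j in seq_len(n_samples)) {
    boost <- spec & pref == meta$habitat[j]
    expected[boost, j] <- expected[boost, j] * sc$fold_enrichment
  }
  counts <- apply(expected, 2, function(e)
    stats::rmultinom(1, sc$depth, e)[, 1])
  dimnames(counts) <- dimnames(expected)

  mu <- matrix(stats::rnorm(sc$n_habitats * length(.env_vars)),
               sc$n_habitats, length(.env_vars),
               dimnames = list(habitats, names(.env_vars)))
  env_values <- sc$env_effect * mu[meta$habitat, , drop = FALSE] +
    matrix(stats::rnorm(n_samples * length(.env_vars)), n_samples)
  rownames(env_values) <- meta$sample_id

  structure(list(
    otu = otu_table(counts),
    meta = meta,
    lattice = lattice,
    env = env_table(env_values, unname(.env_vars)),
    truth = data.frame(otu_id = otu_ids, specialist = spec,
                       preferred_habitat = pref, stringsAsFactors = FALSE),
    scenario = sc), class = "synthetic_community")
}

#' Write a synthetic community to a directory
#'
#' Writes `otu.tsv`, `meta.tsv`, `env.tsv`, `lattice.tsv` and `truth.tsv` in
#' the pipeline's text formats.
#'
#' @param sim a `synthetic_community` from [generate_community()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_community"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(sim$otu, file.path(dir, "otu.tsv"))
  write_sample_metadata(sim$meta, file.path(dir, "meta.tsv"))
  write_env_table(sim$env, file.path(dir, "env.tsv"))
  write_lattice(sim$lattice, file.path(dir, "lattice.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
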