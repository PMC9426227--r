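# habspec

Habitat-specialization analysis for soil microbial communities sampled
across plant community types.

Forest soils host bacterial and fungal communities whose members may be
*habitat specialists* — significantly concentrated in one plant community
type — or neutral generalists. `habspec` implements the statistical
workflow for deciding which, for surveys that sample a few replicate
quadrats per community type on a rectangular lattice and sequence one soil
sample per quadrat. It is aimed at microbial ecologists working with OTU
count tables from such designs, and at anyone who needs a tested,
self-contained implementation of the torus-translation association test at
small lattice scale.

## What it computes

**Torus-translation test** (`torus_test`). For OTU *i* and habitat *h* the
observed statistic is the mean per-cell relative abundance
s(i,h) = (1/|C_h|) Σ_{c∈C_h} x_ic / N_c. The null holds the species map
fixed and slides the habitat map around the torus: all shifts of four map
images (identity, 180° rotation, mirror, mirrored rotation), 4·r·c maps in
total. One-sided add-one p-values with inclusive ties classify each
OTU × habitat pair as positive / negative / neutral; a specialist is
positive somewhere. `summarize_associations` turns the classifications into
the per-kingdom, per-habitat and forest-type percentage tables such studies
report.

**Bipartite modularity** (`build_network`, `optimize_modules`). Barber's
weighted bipartite Q = (1/m) Σ (A_ih − k_i d_h / m) δ(g_i, g_h) on the
OTU–habitat abundance network, with a seeded label-propagation + greedy
move/merge search verified against exhaustive partition enumeration at
small scale.

**Variation partitioning** (`varpart3`, `varpart_env`). Adjusted-R²
inclusion–exclusion over the topography / soil / light predictor sets from
the least-squares step of RDA (Hellinger-transformed community by default):
seven fractions plus residual, closing to 1 exactly.

**Supporting statistics** (`bray_curtis`, `nmds`, `permanova`,
`envfit_centroids`, `accumulation_curve`) and a **synthetic community
generator** (`synthetic_scenario`, `generate_community`) with planted
specialists and a truth table, so the whole pipeline is testable without
sequencing data.

## Worked example

```r
library(habspec)

sim <- generate_community(synthetic_scenario(seed = 1))   # 6 habitats x 3 quadrats,
                                                          # 500 OTUs, 33% specialists
cfg <- pipeline_config(otu = sim$otu, meta = sim$meta, env = sim$env, seed = 1)
report <- run_pipeline(cfg)

report$association_summary$overall
#>   kingdom    group n_tested n_positive pct_positive n_negative pct_neutral
#> 1     all      all      497        255     51.30785        151   36.016097
#> 2     all dominant       38         33     86.84211         16    7.894737

recovery_metrics(report, sim$truth)[c("sensitivity", "habitat_accuracy")]
#> $sensitivity
#> [1] 1
#> $habitat_accuracy
#> [1] 1

report$modularity$Q            # 0.2297536, 6 modules
round(report$varpart$totals, 3)
#> topography       soil      light
#>      0.166      0.348      0.421
report$ordination$permanova$p  # 0.001
```

Reading the numbers: 497 of the 500 simulated OTUs survive the 0.01%
relative-abundance filter; 255 (51%) are positively associated with at
least one habitat at α = 0.05 — every planted specialist is recovered with
its true habitat (sensitivity and habitat accuracy 1), and the excess over
the planted 165 reflects the compositional shadow that strong specialists
cast on other taxa's relative abundances. The negative calls arise the same
way. PERMANOVA confirms the habitat structure (p = 0.001); the variation
partition attributes most explained variation to the (here synthetic)
environment sets.

File-based inputs work the same way: TSV OTU table, metadata, environment
table and optional lattice, or a YAML config via
`run_pipeline("config.yaml")`. `inst/scripts/run_pipeline.R` is a thin
shell wrapper.

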