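---
title: "Testing habitat specialization of soil microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing habitat specialization of soil microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habspec)
```

## The question and the data model

Forest soils host bacterial and fungal communities whose composition may
track the overlying plant community. The question this package addresses is
whether individual microbial taxa (OTUs) are distributed at random across
plant community types ("habitats") or are *habitat specialists* —
significantly more abundant in one community type than a spatial null
allows. The sampling design it targets is a small replicated quadrat survey:
H habitat types (six in the motivating design: two broad-leaved, two
coniferous, two shrub communities) with a fixed number of replicate quadrats
each, every quadrat yielding one sequenced soil sample. The data objects are

* an OTU count table (OTUs × samples, whole non-negative counts),
* sample metadata placing each sample on a rectangular quadrat lattice and
  naming its habitat,
* an environment table of quantitative variables, each tagged
  `topography`, `soil`, or `light`.

Before testing, OTUs with pooled relative abundance below 0.01% are removed
(`filter_rare()`; the boundary value is kept, since only abundances *less
than* the threshold are removed). Species groups are defined on the same
pooled relative abundance: *core* above 10% and *dominant* above 0.5%,
with strict inequalities. The core definition is taken literally even though
a 10% cutoff is ecologically unusual (it yields fewer members than
"dominant" and is often empty); read as "top decile" it would be a
different statistic, so both thresholds are exposed as arguments and the
literal reading is the default.

## The torus-translation test

For OTU $i$ and habitat $h$ the observed statistic is the mean per-cell
relative abundance over the cells carrying $h$:

$$ s_{ih} \;=\; \frac{1}{|C_h|}\sum_{c \in C_h} \frac{x_{ic}}{N_c}, $$

where $x_{ic}$ is the OTU's count in cell $c$ and $N_c$ the cell's
sequencing depth. Depth normalisation replaces the raw stem counts of
forest-census formulations because sequencing depth, unlike census effort,
varies between samples.

The null distribution keeps the species map fixed and slides the *habitat*
map around the torus: every toroidal shift of four images of the map
(identity, 180° rotation, horizontal mirror, mirrored rotation), i.e.
$4\,rc$ maps on an $r \times c$ lattice, of which the untranslated identity
is the observed one and the remaining $4rc - 1$ form the null. Each
translated map preserves habitat areas exactly and preserves the spatial
autocorrelation of both layers, which is the point of the torus device.
One-sided p-values use the add-one rule with ties counted inclusively:

$$ p^{+}_{ih} = \frac{\#\{\text{null} \ge s_{ih}\} + 1}{4rc}, \qquad
   p^{-}_{ih} = \frac{\#\{\text{null} \le s_{ih}\} + 1}{4rc}. $$

An OTU is *positively associated* with $h$ when $p^{+} \le \alpha$
(default $\alpha = 0.05$ per tail, matching the motivating analysis; a
`harms = TRUE` switch applies the 0.025-per-tail convention of the original
forest-plot test), *negatively associated* when $p^{-} \le \alpha$, and
*neutral* otherwise; a *specialist* is positive for at least one habitat.
No multiple-testing correction is applied across OTUs by default (none is
applied in the analyses this mirrors); `p_adjust = "BH"` is available.
Floating-point comparisons between map statistics use a $10^{-12}$
tolerance so that mathematically tied cell subsets summed in different
orders still count as ties.

### Lattice geometry and attainable significance

The survey designs this models rarely record a spatial arrangement for the
quadrats, so the package builds a default lattice from the metadata grid and
offers `lattice_layout()` for simulation. The layout choice is not
cosmetic. With only $4rc = 72$ maps on an 18-cell lattice, any symmetry of
a habitat patch becomes a guaranteed tie: a straight 1×3 replicate run is
mapped onto itself (up to translation) by the rotation and mirror images, so
at least three non-identity maps reproduce the observed statistic exactly
and $p^{+}$ can never drop below $4/72 \approx 0.056$ — no positive call is
then possible at $\alpha = 0.05$ at all. The default `brick` layout
therefore tiles pairs of habitats into 2×3 bricks of L-shaped triominoes,
which have no translation, rotation, or mirror symmetry on the torus: all 72
maps select distinct cell sets, the attainable p-values are
$1/72, 2/72, \dots$, and the exact size of the test at $\alpha = 0.05$ is
$\lfloor 72 \cdot 0.05\rfloor / 72 = 1/24 \approx 0.042$ (slightly less in
count data, where genuine value ties are common among rare OTUs). Any test
with a 72-map exhaustive null has this granularity; validation checks of the
false-positive rate must compare against it rather than against a
continuous 5%. Straight-run (`blocks`) and randomised (`scattered`)
layouts remain available, and a user-supplied `lattice.tsv` overrides
everything.

## The synthetic generator

`generate_community()` emulates the target design so every downstream stage
is testable without sequencing data. Base abundances are lognormal
($\mu = 0$, $\sigma = 1$ on the log scale — the middle of the range
species-abundance fits to amplicon data usually report; $\sigma$ is a
scenario parameter). A configurable fraction of OTUs are specialists, each
assigned one preferred habitat uniformly at random and enriched there by a
fold factor (default 8, a strong but realistic enrichment for genuine
habitat specialists); counts are drawn per sample from a multinomial at
fixed depth (default 20,000 reads), so column sums are exact and the data
are compositional, like real amplicon libraries. Environment variables are
habitat-specific Gaussian means scaled by `env_effect` plus unit noise,
tagged into the three canonical groups. The truth table (specialist status,
preferred habitat) is a first-class output so recovery metrics are joins,
not re-simulations.

Two features of real data are deliberately *not* simulated: read-level
artefacts (chimeras, PCR bias) and taxon–taxon interactions. One real
feature emerges on its own: because composition must sum to one, strong
specialists depress every other OTU's relative abundance in their preferred
habitat, so non-specialists acquire weak apparent habitat structure in
strong-signal scenarios. Passing recovery tests therefore demonstrates
sensitivity and habitat assignment, not per-OTU specificity under strong
compositional distortion; the type-I-error study uses the specialist-free
null (`null_scenario()`), where no such distortion exists.

## Bipartite modularity

The community–microbe network has OTUs on one side, habitats on the other,
and edge weights equal to pooled abundance (per-habitat relative abundance
by default). Barber's bipartite modularity

$$ Q = \frac{1}{m} \sum_{i,h} \left(A_{ih} - \frac{k_i d_h}{m}\right)
       \delta(g_i, g_h) $$

is implemented in weighted form (weights are abundances; a `presence`
option binarises). The module search is a label-propagation-style greedy:
columns seed their own modules, rows join their strongest column module,
then single-node moves and pairwise module merges run to a local optimum,
restarted from random initialisations; the best partition over restarts is
returned, never with $Q$ below the single-module value of 0. Module count
is emergent — habitats may share modules — not fixed to the habitat count.
Exhaustive enumeration over all set partitions verifies the search returns
the global optimum on networks of up to ten nodes; at realistic scale it is
a heuristic, like every modularity optimiser.

## Variation partitioning

Community variation is partitioned among the three environment groups by
adjusted $R^2$ from the multivariate least-squares step of RDA, with
Ezekiel's adjustment, and inclusion–exclusion over the seven predictor
subsets; the seven fractions plus residual sum to one identically. The
community table is Hellinger-transformed first — the analyses this mirrors
do not state their transform, and Hellinger is the standard choice that
makes Euclidean RDA appropriate for abundance data (`chord` and `none` are
available). Negative fractions are reported but flagged, matching the
convention of not displaying values below zero. With n = 18 samples and 15
predictors the full model retains 2 residual df; when predictors reach
$n - 2$ the package forward-selects within each set (by adjusted $R^2$,
logged, and switchable off) rather than fitting a saturated model.

## Supporting statistics

Bray–Curtis dissimilarities come from `vegan::vegdist`; NMDS is
`vegan::metaMDS` on the precomputed distance matrix with
`autotransform = FALSE` — the automatic community transforms and wisconsin
standardisation of `metaMDS`'s default pipeline are deliberately not
replicated, since filtering and distance choice are explicit pipeline
stages here. PERMANOVA is the one-way distance-based pseudo-F with free
label permutation (no strata, matching the single-factor design), add-one
p-values, and optional exhaustive enumeration of all $n!$ labellings for
small n; note that with three replicates per group the permutations that
preserve a two-group split tie the observed statistic, so the attainable
floor at $n = 6$ is $72/720 = 0.1$ — another granularity consequence the
tests assert rather than fight. Habitat centroids on ordination coordinates
are fit as $R^2 = 1 - SS_w/SS_t$ with permutation p. The species
accumulation curve uses the exact hypergeometric estimator
$E[S(t)] = \sum_i \bigl(1 - \binom{T - T_i}{t}/\binom{T}{t}\bigr)$,
computed on log-binomials for stability.

## Validation scale and determinism

The test suite validates each component against independent oracles (nested
loop enumerations, all-subset and all-partition sweeps, closed forms, and
vegan's own implementations where they exist) at small problem sizes, and
the statistical properties at moderate ones: the type-I study uses 20
seeded habitat-free communities of 500 OTUs at 20,000 reads; the recovery
study uses fold-8 enrichment at 50,000 reads; the modularity direction
study uses 20 paired seeds at 33% vs 85% specialists — sizes chosen so the
whole suite runs in well under a minute per study while keeping binomial
uncertainty far smaller than the margins being asserted. All randomised
stages take explicit seeds, and `run_pipeline()` derives stage seeds from
one master seed, so identical configurations produce byte-identical
reports.

## Worked example

```{r example, eval = FALSE}
sim <- generate_community(synthetic_scenario(seed = 1))
cfg <- pipeline_config(otu = sim$otu, meta = sim$meta, env = sim$env,
                       seed = 1)
report <- run_pipeline(cfg)
report$association_summary$overall
recovery_metrics(report, sim$truth)
```

## Known limitations

* The torus null needs a gap-free rectangular lattice; irregular or missing
  quadrats are not supported.
* With 18 cells the null has 72 maps; p-value granularity (multiples of
  1/72) is irreducible at that scale.
* The module search and NMDS are local optimisers; both are seeded and
  restarted but only oracle-verified at small scale.
* Specificity of the torus test degrades under extreme compositional
  distortion (many strong specialists), which is a property of relative
  abundance data, not of the test; absolute-abundance calibration is out of
  scope.
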