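---
title: "Connectivity-based parcellation and cross-species asymmetry analysis with connAsym"
author: "connAsym authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based parcellation and cross-species asymmetry analysis with connAsym}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connAsym)
```

## The scientific problem

Hemispheric specialization — language lateralized to the left, visuospatial
attention to the right — is a hallmark of the human brain, and the inferior
parietal lobule (IPL) is among the most asymmetric and most evolutionarily
expanded association regions. A comparative strategy for studying how such
specialization arose is to (i) subdivide the region by the similarity of its
anatomical connectivity fingerprints (connectivity-based parcellation),
(ii) quantify left–right differences of volume and of connectivity at
several granularities with a common asymmetry index, and (iii) relate
subregion volume to total brain size across species through allometric
scaling. `connAsym` implements this entire analysis chain as reusable,
deterministic R functions, together with a synthetic-data generator that
plants known cluster structure, connectional asymmetries and scaling
exponents, so that every stage can be validated by parameter recovery
without any neuroimaging download.

## Data model

The central container is `ConnAsymExperiment`, a thin extension of
`SummarizedExperiment`: rows are seed vertices of the region under study,
columns are whole-brain target bins, and each assay holds one
subject-hemisphere matrix of non-negative connectivity values (an analogue
of probabilistic-tractography streamline counts). Seed index *i* on the
left corresponds to mirrored index *i* on the right; no surface geometry or
registration is modelled — homotopy is by index construction, which is what
the synthetic generator produces and what index-corresponded real data
would provide.

## The synthetic generator

A `SpeciesSpec` fixes one cohort completely. Connectivity: row *i* of each
subject-hemisphere matrix is drawn around the mean fingerprint of its
planted cluster with additive Gaussian noise truncated at zero (keeping
values non-negative, as count-derived probabilistic values are); right-hemisphere
rows are then multiplied element-wise by per-cluster, per-target effects,
so an effect of 1 is perfect symmetry, values below 1 plant leftward
(negative-AI) asymmetry, and the noise-free right row is exactly
`effect × left row`. Volumes: per subject, total gray-matter volume (GMV)
is drawn log-uniformly in the species range; each subregion's bilateral
mean volume follows `exp(b) · GMV^a`, is split between hemispheres so the
asymmetry index equals the planted value exactly, and each hemisphere is
then perturbed by independent lognormal noise (the standard noise model in
allometry). The independent per-hemisphere noise is deliberate: if the
left/right split stayed exact, every subject would carry the identical AI
and the downstream signed-rank tests would be degenerate — with
per-hemisphere noise the observed AI fluctuates around the planted value,
which is the situation the statistics are designed for. With zero noise
all planting identities hold exactly, and identical `(spec, seed)` pairs
reproduce a dataset bit-identically.

Three presets (`presetSpec()`) mirror the qualitative comparative pattern
the pipeline is designed to detect. All share a 60-seed, 4-block,
300-target geometry with positive-allometry exponents (1.15–1.30):

* `"macaque-like"` (n = 8): no connectional and no volumetric asymmetry —
  the null species;
* `"chimp-like"` (n = 27): a handful of asymmetric connections (18
  targets) and volumetric AIs of −0.12, −0.10, +0.10, +0.12 across the
  four subregions (anterior leftward, posterior rightward);
* `"human-like"` (n = 40): widespread asymmetric connections (75 targets,
  stronger effects, both directions) and the same volumetric sign pattern
  with larger magnitudes.

Two design details matter. Each cluster owns a high-connectivity band of
targets, and all clusters share a 20-target "anchor" carrying the global
maximum; because max-normalization divides each hemisphere's matrix by its
own maximum, the anchor pins both hemispheres to a common reference so
that planted multiplicative effects (which never touch the anchor and
never exceed it) cannot shift the normalization and leak spurious
asymmetry into unaffected targets. Second, the per-subject connectivity
noise (sd 10 against band values of 80) leaves within-block row
correlations around 0.9 and between-block correlations near 0.1 — strong
but not degenerate cluster structure. Cohort sizes follow what comparative samples of this kind typically
offer (8 macaques, 27 chimpanzees, 40 humans); per-subject connectivity
variance has no published reference value, so the noise scale is a
package choice, exposed in the spec.

What the generator does *not* emulate: diffusion signal, streamline
geometry, registration error, spatial autocorrelation along the cortical
surface, and distance-dependent tractography bias. Passing recovery tests
on these synthetics therefore validates the statistical machinery, not the
tractography; on real data the same functions apply but the error
structure is richer.

## Profile processing

Raw matrices are processed in the fixed order log-transform →
max-normalize → (optional) smooth → threshold. The log-transform is
`log(1 + x)` so zeros map to zero and sparsity is preserved (the choice of
offset is the package's; only "log-transform" is standard). Division by
the matrix maximum puts values in [0, 1]; the operation is idempotent at
the object level via the `normalized` flag. Metric smoothing kernels have
no meaning without geometry, so smoothing is `rounds` of graph-neighborhood
averaging over an explicit seed adjacency, with the uniform edge weight
`1/d_max` and the remainder on the self-loop — a symmetric, doubly
stochastic operator, so the per-target sum over seeds is conserved
(default `rounds = 0`). Population maps are across-subject means
thresholded strictly (`> t` retained); the per-species defaults 0.5 / 0.2
/ 0.3 reflect the data-quality-dependent choices customary for human,
chimpanzee and macaque cohorts and are plain configuration values, not
derived quantities. The vertex-wise
analysis mask is the union of the left and mirrored-right map supports.

## Parcellation

Seed-by-seed Pearson correlation of normalized fingerprints gives a
subject similarity matrix; group matrices are element-wise means.
Clustering is normalized-Laplacian spectral clustering: correlations are
mapped to affinities by the monotone shift `(r + 1) / 2` ((a
cross-correlation can be negative and an affinity cannot); clipping at zero
is available as `affinity = "clip"`), the leading *k* eigenvectors of
`D^{-1/2} A D^{-1/2}` are row-normalized, and k-means with a fixed seed
and at least 10 restarts labels the seeds. Labels are relabelled
canonically (cluster 1 holds the lowest seed index, ascending by first
occurrence), which makes outputs reproducible and diffable. Constant rows
receive zero correlation to all other seeds, with a warning.

Cluster counts are scanned (default k = 2…12) and scored by cross-group
consistency: all groups are parcellated at each k, labels are matched by
the Hungarian method on the co-occurrence table, and the score is the mean
pairwise adjusted Rand index, clamped to [0, 1]. The chosen k is the
largest k whose score reaches τ (default 0.8), falling back — flagged — to
the argmax when none does. This operationalizes "the largest number of
subregions with a coherent topological organization across groups".

One structural property deserves emphasis, because it drove the design of
the shipped consistency fixture. If all groups contain the *same* k*
equal-sized, internally homogeneous blocks, then at k* + 1 every group
splits one block along noise, and the mean pairwise ARI between two such
partitions is ≈ 0.85 — above the default τ. The maximum-coherent-k rule
therefore cannot distinguish k* from k* + 1 in that idealized situation.
What makes the rule work — in the comparative setting that motivated it —
is that the *finer* structure diverges across groups ((comparative parcellations typically find the extra
fifth cluster emerging in different positions in different species)). `concordantGroupFixture()` reproduces exactly
this situation: groups share four blocks of unequal size, and each group
carries a mild subdivision of a *different* large block; at k = 4 all
groups agree (score 1.0), at k = 5 each confidently splits its own block
and the score collapses to ≈ 0.75, so the scan stops at 4. Conversely,
`runPipeline()` on the three homogeneous presets may legitimately report
k = 5 — a faithful reflection of the criterion's behaviour, not an error.

## Asymmetry statistics

All levels use the asymmetry index `AI = 2(R − L)/(R + L)`: antisymmetric,
confined to [−2, 2], zero at L = R, negative for leftward dominance, and
missing where `L + R = 0`.

**Vertex level.** Per-subject AIs of each subregion's fingerprint are
tested against zero with a one-sample t statistic whose null is generated
by sign flips (valid when the null distribution of AIs is symmetric about
zero). All `2^n` flips are enumerated when `2^n ≤ nPerm`; otherwise
`nPerm` Monte Carlo flips are drawn, the identity flip is always counted,
and `p = (1 + #{|t*| ≥ |t|})/(1 + nPerm)`, which is a valid estimator
bounded below by `1/(nPerm + 1)`. Benjamini–Hochberg q-values are computed
across the mask (per subregion); all-missing units are excluded from the
family. Cohen's d (`mean / sample sd`, n − 1 denominator) is reported per
unit. Degenerate cases are pinned: all-zero data give p = 1, d = 0;
constant non-zero data give |t| = ∞, handled consistently across flips by
clamping numerically-zero variances.

**ROI, tract and volumetric levels.** Region values are plain means of
fingerprint connectivity over target-index sets (anatomical atlases and
tract protocols are out of scope; regions are index sets). Left/right
pairs are compared with a two-sided Wilcoxon signed-rank test: zero
differences are discarded (classical; their count is reported — the Pratt
variant is available), the null is enumerated exactly over all `2^n` sign
assignments of the ranks for n ≤ 12 (ties included, via midranks), and a
tie-corrected normal approximation with continuity correction is used
beyond. Bonferroni correction uses the explicit family size m = subregions
× regions within a species; whether to additionally multiply across species is
a genuine modelling choice, so it is exposed as
`familyMultiplier` with the per-species default. The vertex-level test
operates on AI values (the quantity the index defines); testing raw
`R − L` differences instead is available via `aiOn = "diff"`.

## Allometry

Scaling is fitted by ordinary least squares of `log(volume)` on
`log(GMV)` (natural logs; the base cancels in the slope, which is the
scaling exponent — above 1 is positive allometry). Reduced major axis
regression, common in allometry when both variables carry error, is
available but not the default, which is ordinary linear regression; the
pooled fit can use per-species mean data points (default, matching
regression on species averages) or all subjects. Hemisphere slope
equality is tested as the interaction F-test in the stacked model
`log(volume) ~ log(GMV) × hemisphere`; the two hemispheres of the same
subjects are treated as independent samples in this comparison — a
plot-level simplification inherited from the comparative design and a
documented limitation (a subject-level mixed model would be the stricter
alternative). Identical left and right inputs return F = 0, p = 1 with a
degenerate-fit warning. Note that when planted volumetric AIs differ
*across species* (as in the chimp/human presets versus the macaque null),
the pooled interaction test can legitimately reject slope equality: a
species-dependent L/R ratio correlated with GMV is a real slope
difference in the pooled model.

## Numerical choices and problem sizes

Similarity matrices are validated symmetric within 1e-10 with unit
diagonal; eigendecompositions use `eigen(symmetric = TRUE)`; k-means uses
≥ 10 restarts under an explicit seed; Hungarian matching breaks ties
toward the lowest label pair. Exact-test enumeration limits are 2^20 sign
vectors (permutation) and n = 12 (signed rank). The validation suite runs
at deliberately modest sizes — 400-seed similarity fixtures, 20 × 200
permutation nulls at 1000 flips, 200–500 replicate calibrations at n = 75
— chosen so the full suite completes in well under a minute while keeping
binomial confidence bands around calibration rates tight enough to be
meaningful (±1.5–2 percentage points).

## Reproducibility

Every RNG consumer takes an explicit seed; `runPipeline()` validates this
before any computation, logs one line per stage (parameters, seed, output
checksums) and writes only plain-text TSV/JSON artifacts, so re-running a
configuration reproduces byte-identical outputs. The pipeline
configuration round-trips losslessly through YAML.

## Worked example

```{r example, eval = FALSE}
library(connAsym)

## simulate the three species-like cohorts and run everything
cfg <- defaultPipelineConfig(outputDir = "connasym-output", nPerm = 1000)
rep <- runPipeline(cfg)

rep$chosenK                # selected cluster number
rep$significantCounts      # significant asymmetries per species and level
rep$allometry$fits         # pooled log-log scaling per subregion/hemisphere
```

## Known limitations

* Homotopy is positional (index i left ↔ index i right); real data need a
  cross-hemisphere surface correspondence before these functions apply.
* No spatial statistics: per-vertex tests with FDR, not cluster-extent or
  threshold-free enhancement; target units are treated as exchangeable.
* The ANCOVA treats hemispheres as independent samples (see above).
* The consistency criterion cannot reject k* + 1 when groups share
  perfectly homogeneous equal blocks; divergent finer structure across
  groups is what identifies the planted k.
* Anatomical naming of clusters, ROIs and tracts is interpretive and out
  of scope; the package works with index sets.
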