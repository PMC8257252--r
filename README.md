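# connAsym

Connectivity-based parcellation and cross-species hemispheric asymmetry
analysis.

## What it is for

Comparative neuroanatomy asks how the hemispheric specialization of
association cortex — most prominently the inferior parietal lobule (IPL),
a hub for language and tool use — arose across primates. A standard
analysis chain is:

1. **Connectivity-based parcellation.** Each seed vertex of the region
   carries a whole-brain connectivity fingerprint (an M × N matrix per
   subject and hemisphere). Pearson correlation between fingerprints gives
   an M × M similarity matrix; after group averaging, normalized-Laplacian
   spectral clustering subdivides the region, scanning k = 2…12 and
   choosing the largest k whose parcellation is consistent across groups
   (mean pairwise adjusted Rand index after Hungarian label matching).
2. **Asymmetry statistics.** Left–right differences are measured by the
   asymmetry index **AI = 2 (R − L) / (R + L)** (negative = leftward) and
   tested at four levels: per-subregion volumes and region/tract mean
   connectivity with exact two-sided Wilcoxon signed-rank tests and
   Bonferroni correction, and vertex-wise connectivity on a
   population-tractogram mask with one-sample sign-flip permutation
   t tests, Benjamini–Hochberg FDR, and Cohen's d.
3. **Allometric scaling.** Subregion volume against total gray-matter
   volume in log-log space, `log V = b + a · log G` (a > 1: positive
   allometry), pooled across species, with an ANCOVA interaction F-test
   for slope equality between hemispheres.

`connAsym` implements this chain as deterministic, seed-explicit R
functions in Bioconductor style (the data container extends
`SummarizedExperiment`), together with a synthetic-data generator that
plants known cluster structure, connectional asymmetries and scaling
exponents — so the whole pipeline is testable by parameter recovery
without any imaging data. Three shipped presets (`"macaque-like"`,
`"chimp-like"`, `"human-like"`) encode the qualitative comparative
pattern: no asymmetry in the null species, an anterior-leftward /
posterior-rightward volumetric pattern plus a few asymmetric connections
in the chimp-like cohort, and the same pattern with widespread asymmetric
connections in the human-like cohort.

## Worked example

```r
library(connAsym)

ds <- simulateDataset(presetSpec("human-like"), seed = 7)
tab <- runAsymmetryBattery(ds,
  roiSets   = defaultRegionSets(300, 11, "roi"),
  tractSets = defaultRegionSets(300, 7, "tract"),
  config    = batteryConfig(nPerm = 1000, threshold = 0.5, seed = 1))

tab[tab$level == "volumetric", ]
#>  subregion  n ai_mean statistic        p    p_adj     d significant
#>          1 40 -0.1515         0 3.71e-08 1.48e-07 -3.31        TRUE
#>          2 40 -0.0875         0 3.71e-08 1.48e-07 -1.99        TRUE
#>          3 40  0.0894       819 4.00e-08 1.60e-07  2.29        TRUE
#>          4 40  0.1560       820 3.71e-08 1.48e-07  3.32        TRUE

sum(tab$significant[tab$level != "volumetric"])
#> [1] 89
```

The four subregions recover the planted volumetric sign pattern
(−, −, +, +): the anterior two are leftward-asymmetric, the posterior two
rightward, each highly significant after Bonferroni correction over the
four-subregion family (`p_adj`), with large one-sample effect sizes
(`d` = mean AI / sd). The 89 significant connectional units (vertex, ROI
and tract levels combined, planted: 75 vertex targets plus the regions
they fall in) are what "widespread asymmetric connectivity" means for this
cohort; the same battery on the chimp-like preset finds ~20, and on the
macaque-like preset none.

Per-subregion allometry from the same dataset:

```r
v1 <- subset(volumeTable(ds), subregion == 1)
allometricFit(v1$left_vol, v1$gmv)
#> AllometryFit: slope 1.0869 [0.9707, 1.2030], intercept -6.4734, R^2 0.9043, n 40
```

(One species alone spans too little of the GMV axis to pin the exponent —
the planted 1.15 sits inside the wide CI; the pooled three-species fit in
`runPipeline()` / `allometryTable()` tightens it.)

The full pipeline — simulate all three cohorts, parcellate, scan k, run
every asymmetry level, fit pooled allometry, write TSV/JSON artifacts and
a log with checksums — is one call:

```r
rep <- runPipeline(defaultPipelineConfig(outputDir = "connasym-output"))
rep$significantCounts
```

## Documentation

The methods vignette (`vignettes/connAsym-methods.Rmd`) describes the
model and its assumptions, what the synthetic generator does and does not
emulate, the statistical conventions (sign-flip estimator, zero-difference
and tie handling, correction families), the numerical choices, and known
limitations.
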