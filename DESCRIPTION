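Package: connAsym
Title: Connectivity-Based Parcellation and Cross-Species Hemispheric
    Asymmetry Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying hemispheric specialization of an
    association-cortex seed region (such as the inferior parietal lobule)
    from anatomical connectivity. Provides similarity-based spectral
    parcellation of seed-vertex connectivity fingerprints with a
    cross-group cluster-number scan, asymmetry-index statistics at the
    vertex, region-of-interest, tract and volumetric levels (sign-flip
    permutation tests with false-discovery-rate correction and Cohen's d;
    exact Wilcoxon signed-rank tests with Bonferroni correction), and
    allometric log-log scaling regression with ANCOVA slope comparison
    between hemispheres. A synthetic-data generator with planted cluster
    structure, connectional asymmetries and scaling exponents makes the
    whole pipeline testable without neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    mclust,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: StatisticalMethod, Clustering, Regression
RoxygenNote: 7.3.3
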