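Package: taphofidelity
Title: Live-Dead Compositional Fidelity Analysis for Multi-Taxic Benthic
    Assemblages
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the compositional and diversity fidelity of death
    assemblages relative to sympatric live communities across higher taxa.
    Provides element-corrected abundance tables, rarefaction-based sample
    standardization of live-dead pairs, the three standard fidelity
    statistics (Spearman rank correlation of proportional abundance,
    Pearson correlation, Bray-Curtis similarity) with accelerated
    bias-corrected (BCa) bootstrap confidence intervals, a perfect-fidelity
    randomization null model that isolates sampling effects, diversity
    comparisons across assemblage subsets (Kruskal-Wallis with Bonferroni
    correction), and a modified homogeneity-of-multivariate-dispersions
    (HMD) analysis decomposing live-dead variation into premortem and
    postmortem components.  A forward taphonomic simulator (species
    abundance distributions, site heterogeneity, time-averaging,
    differential preservation, multi-element skeletons) generates complete
    study datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vegan,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'io.R'
    'preprocess.R'
    'standardize.R'
    'fidelity.R'
    'resampling.R'
    'diversity.R'
    'hmd.R'
    'synthetic.R'
    'pipeline.R'
    'show-methods.R'
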