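Package: endotrack
Title: Quantification of In Vivo Axonal Transport of Signaling Endosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying fast retrograde axonal transport of
    signaling endosomes from single-particle track tables, as produced by
    manual or automated spot tracking of intravital imaging movies.
    Implements track inclusion filtering, frame-to-frame step speeds,
    pause-run detection, per-animal aggregation of speed and pausing
    metrics, axon-caliber estimation from punctum widths, and a
    normality-gated statistical decision tree (D'Agostino-Pearson omnibus
    gate; t / ANOVA with Dunnett comparisons against a control versus
    Mann-Whitney / Kruskal-Wallis with Dunn comparisons) with the animal
    as the unit of inference. A two-state run-and-pause Markov simulator
    generates synthetic cohorts with genotype- and neuron-class-dependent
    motility for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    multcomp,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
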