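Package: fluidgsea
Title: Running-Sum Gene Set Enrichment for Paired Two-Colour Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene set enrichment analysis for paired two-colour microarray
    profiles, built around the unweighted running-sum (Kolmogorov-Smirnov
    type) enrichment score on a log-ratio-ranked gene list with a
    gene-order permutation null. Includes readers for GMT gene-set
    collections and GAF 2.x annotation files, probe-to-gene collapsing of
    log2(Cy5/Cy3) ratios with per-gene t-tests, per-direction ranking of
    whole collections, cross-sample enrichment tables and focal
    pathway/gene reports, and a synthetic-study generator that plants
    directional enrichment signal for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
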