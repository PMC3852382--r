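Package: stressgate
Title: Simulation and Mapping of Combined-Stress QTL Architectures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how quantitative trait loci (QTL) combine
    two abiotic stress inputs (drought and ultraviolet radiation) into
    growth phenotypes. Simulates recombinant inbred line (RIL) and nested
    association mapping (NAM) genotypes under a Haldane map function, and
    phenotypes generated by QTL acting through logic-gate signal
    combination rules (independent, AND, OR, XOR, attenuating modifier).
    Provides per-marker genotype-by-environment interaction scans with
    per-environment allele-effect estimates, rank-based P-value smoothing
    with Simes or Fisher window combination and false-discovery-rate
    control, joint forward stepwise selection for multiparent designs with
    a simulation-based calibration of the entry threshold, variance
    component estimation of the line (genotype) share of phenotypic
    variance, classification of cross-environment allele-effect patterns
    against logic-gate theory, and a permutation test for genomic interval
    overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    car,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
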