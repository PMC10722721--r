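Package: hybridclines
Title: Bayesian Genomic Cline Analysis of Admixed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping restricted and biased introgression in hybrid
    zones from genome-wide biallelic genotypes. Estimates per-individual
    hybrid indices and per-locus logit-logistic genomic clines (steepness v,
    centre c) by adaptive Markov chain Monte Carlo, compares full against
    neutral (v = 1) cline models with the widely applicable information
    criterion (WAIC), calls steep-cline variants and pools them into
    candidate regions of restricted introgression, and provides the
    downstream association statistics (multi-population Weir-Cockerham FST,
    variant-effect regression, SNP/indel comparison, recombination-category
    contrasts). Includes a hybrid-zone genotype simulator with known
    per-locus cline parameters for validation, and tidyverse-style
    interfaces: tibbles in and out, broom-style tidiers, and ggplot2
    autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    S4Vectors,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    ape,
    coda,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
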