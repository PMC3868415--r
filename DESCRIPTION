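Package: gwasdesign
Title: Design Calculators and Simulators for Genetic Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculators and seeded simulators for the population-genetic
    quantities that drive the design and interpretation of genome-wide
    association studies: allele-frequency-dependent bounds on the r-squared
    measure of linkage disequilibrium; sensitivity and positive predictive
    value of variant-discovery designs under a folded site-frequency
    spectrum; allelic case-control chi-square power, required sample sizes
    and the 1/r-squared sample-size inflation factor together with exact
    multi-locus haplotype models in which the factor fails; and confounding
    diagnostics for case-control sampling from structured populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
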