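Package: triotriage
Title: Trio Genome-Sequencing Variant Triage and Diagnostic Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mode-of-inheritance filtering and tiered prioritization of
    small variants in patient-parent trios, triage of copy-number variants,
    short tandem repeat expansions, runs of homozygosity and mitochondrial
    variants, and classification of per-patient diagnostic outcomes with
    cohort-level concordance analysis between two diagnostic pathways.
    Includes a synthetic trio-cohort generator with planted causal variants
    and a truth table so the whole pipeline is testable without patient
    data, plus parsers for ISCN-like copy-number and repeat notation.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
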