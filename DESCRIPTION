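Package: riboselect
Title: Selection Dynamics and Sequence Analysis for In Vitro Ribozyme
    Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and analysing in vitro selection
    experiments that enrich ligand-responsive self-cleaving ribozymes from
    degenerate libraries. Implements IUPAC library enumeration and
    phenotype classification, a cleavage-based fitness metric with
    deterministic and stochastic models of round-by-round enrichment,
    quantification of cleaved fractions and fitness from gel band
    intensities, variant counting and enrichment-ratio estimation from
    amplicon sequencing reads, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
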