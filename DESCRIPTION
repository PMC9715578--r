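Package: camevol
Title: Genome Evolution and Diel Expression Analysis for CAM Succulents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of the comparative-genomics and
    diel-transcriptomics analyses used to characterise succulent (CAM) plant
    genomes: exact binomial testing for group-specific orthogroup expansion and
    contraction, tandem-duplicate array detection from gene order and homology,
    collinear-block chaining and duplication classification, Nei-Gojobori (NG86)
    Ka/Ks estimation with Jukes-Cantor correction and Ks-peak dating, LTR
    retrotransposon insertion-age estimation, polynomial-regression rhythmicity
    detection and CAM-gene classification from diel expression, and IUPAC
    circadian cis-element scanning with enrichment testing. Ships a synthetic
    data generator that plants recorded ground truth in every input class so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
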