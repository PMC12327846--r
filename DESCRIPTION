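Package: chapkit
Title: Kernel-Convolution Peak Calling and Regulon Analysis for ChAP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Peak calling for chromatin affinity purification sequencing
    (ChAP-Seq) of bacterial transcription factors, built around a
    Mexican-hat (negated second-derivative-of-Gaussian) convolution
    detector with automatic peak-width estimation and background-mass
    normalization. Includes PCR-duplicate collapsing and coverage
    computation from alignments, replicate consolidation with support
    counts, Pearson reproducibility matrices, regulon comparison between
    regulators, peak-to-TSS annotation with upstream/intragenic
    classification, position weight matrix scanning with exact
    dynamic-programming p-values, correlation of binding intensity with
    differential expression, and a seeded synthetic-data generator that
    plants ground-truth binding sites on toy circular genomes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
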