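Package: chromaforge
Title: Hi-C Contact Matrix Processing, Normalisation and Chromatin Architecture Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for chromosome-conformation-capture (Hi-C) data: in-silico
    restriction digestion and ligation-junction handling, read-pair artefact
    filtering with diagnostic statistics, binned sparse contact matrices with
    Knight-Ruiz and iterative-correction balancing, expected-value (distance
    decay) profiles and observed/expected transforms, A/B compartment
    eigenvectors with saddle profiles and compartment strength, insulation
    score and directionality index with TAD boundary calling, a
    local-neighbourhood Poisson loop caller with lambda-chunked FDR,
    aggregate (pileup) analyses, sample comparison (difference and fold-change
    matrices and tracks, matrix PCA), and a deterministic synthetic data
    generator with ground-truth tables. Results are tibbles throughout, with
    broom-style tidiers and ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    methods,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    Rsamtools,
    patchwork,
    optparse
Config/testthat/edition: 3
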