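Package: netdecay
Title: Comparing Evolutionary Rates of Transcriptional Network Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A statistical framework for asking whether different animal
    lineages diverge at the same rate, applied to successive layers of the
    transcriptional network: genome segment retention, nucleotide identity,
    gene-specific transcription factor (GSTF) occupancy, cis-regulatory motif
    retention and mRNA expression correlation. Cross-species similarity is
    modelled as an exponential decay over divergence time; a lineage-naive fit
    is tested against a lineage-aware fit with a likelihood ratio test, and a
    difference is called only when it is both significant and larger than an
    effect-size threshold at 100 million years. The package also provides a
    power simulation for the framework, synthetic-clade generators (genomes
    under substitution/indel/segment loss with ground-truth chain maps, ChIP
    read sets, expression tables, implanted motifs), UCSC-chain coordinate
    lifting with one-to-one filtering, segment-retention sampling,
    nucleotide-resolution occupancy profile correlation with mappability
    masking, a peak-pipeline sensitivity grid, and a position-weight-matrix
    motif retention statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    generics,
    ggplot2,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
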