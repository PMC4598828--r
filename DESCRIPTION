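Package: methdiv
Title: Whole-Genome Bisulphite Methylome Divergence Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of whole-genome bisulphite sequencing methylomes for
    pairs of cultivars or strains: binomial methylation calling against a
    non-conversion error null estimated from an unmethylated control contig,
    CG/CHG/CHH context classification from the reference genome, detection of
    differentially methylated regions (DMRs) in fixed 100-bp bins by Fisher's
    exact test with multiple-testing correction, association of DMRs with
    genes and transposable elements, integration with gene expression
    (directional enrichment, on/off classification, TE density by gene class)
    and with small-RNA loci (overlap and enrichment statistics), metagene and
    chromosome-density profiles, and a fully self-contained synthetic cohort
    generator with planted ground truth for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
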