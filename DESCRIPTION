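Package: spliceratio
Title: Genome-Wide Splicing-Defect Quantification from Intron/Exon Read Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies genome-wide mRNA splicing defects from aligned RNA-seq
    reads. For every intron-containing gene the pipeline counts reads
    overlapping exons and derived introns, forms the intronic/exonic read
    ratio (I/E) and RPKM expression level per condition, compares conditions
    with a signed diagonal-distance statistic (the perpendicular distance
    from the point (I/E_x, I/E_y) to the identity line y = x) tested with a
    Student's t-test, and classifies per-gene change and restoration under
    genetic rescue. A synthetic-data generator emulates aligned reads drawn
    from mixtures of spliced and unspliced transcripts so the whole analysis
    can be exercised and validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    methods,
    tools,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    withr
Config/testthat/edition: 3
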