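Package: lncregulon
Title: Shortlist Transcription-Factor-Regulated lncRNAs from ChIP-Seq and Knockdown RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for nominating long non-coding RNAs
    (lncRNAs) directly regulated by a transcription factor. ChIP-seq peaks
    are ranked by peak height over peak width, background peaks below the
    first quartile of that score are discarded, and surviving peaks are
    assigned to gene promoters within a fixed distance of the
    transcription start site. A two-group negative-binomial Wald test (or
    any externally produced differential-expression table) provides the
    knockdown evidence arm, filtered on absolute log2 fold change and
    Benjamini-Hochberg adjusted p-value. The two evidence sets are
    intersected into a directional candidate-regulon report in which loss
    of expression upon knockdown marks a candidate TF-activated target
    and gain marks a candidate TF-repressed target. A synthetic-data
    module plants ground-truth bound and regulated lncRNAs so that every
    stage, and end-to-end recovery, is testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    DESeq2,
    optparse
Config/testthat/edition: 3
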