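Package: parenthist
Title: Strand-Resolved Analysis of Parental Histone Inheritance
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies how parental (pre-existing) histones are handed
    down through DNA replication and cell division. Implements the eSPAN
    Watson/Crick strand-bias statistic with its masking, control
    normalization, smoothing and origin-centered aggregation;
    reads-per-million and spike-in normalized CUT&RUN/CUT&Tag density
    time-courses, metagene profiles by expression quartile and genome-wide
    correlation matrices; and live-cell SNAP pulse-chase quantification
    with offset- or geminin-based cell-cycle phase calling. A synthetic
    replication-fork and histone-transfer simulator with known ground
    truth makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
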