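Package: phagephase
Title: Temporal Transcriptome Analysis of Phage Infection Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual RNA-seq time courses of lytic
    bacteriophage infection. Implements Total-Count normalization of
    per-gene read-count (TGR) matrices, classification of phage genes into
    early/middle/late/constitutive temporal classes from phase-averaged
    expression profiles, threshold-based differential-expression calling of
    the host response against an uninfected control (log2 fold-change gate
    combined with a 2-standard-deviation control rule and a pooled-variance
    t-test between phases), strand-specific fixed-width genome coverage
    binning, and detection of unannotated antisense and intergenic
    transcripts from strand-specific coverage. A negative-binomial
    synthetic-data generator emulates the dual-organism time-course design
    with known ground truth so every stage has a recovery test.
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
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
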