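Package: guidephase
Title: CRISPR Guide Activity and Nucleosome Occupancy in Pooled Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores sgRNA phenotypes from pooled CRISPR(i) screen count
    tables, calls hit genes with a rank-based composite score, normalizes
    phenotypes into per-gene activity scores, builds TSS-relative activity
    and nucleosome-occupancy profiles with zero-phase Butterworth smoothing
    and peak/trough quantification, and tests the association between guide
    activity and target-site nucleosome occupancy with binned rank tests and
    multi-feature linear models. Includes a synthetic-data generator that
    emulates phased occupancy tracks, tiling sgRNA libraries, and
    negative-binomial screen counts with ground truth, so the whole pipeline
    runs and is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
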