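Package: trackenrich
Title: Overlap Enrichment Statistics for Genomic Annotation Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests whether one set of genomic intervals (for example
    disease-associated regions or SNPs from a genome-wide association
    study) co-localizes with another (for example chromatin-state
    segmentations) more than expected by chance.  Implements coverage
    enrichment ratios, Monte Carlo permutation nulls that exactly
    preserve the empirical segment and inter-segment length
    distributions of a track, global and chromosome-arm binned testing
    with Benjamini-Hochberg false discovery rate control, case-control
    differential-track label-permutation tests, point-in-state tests,
    construction of fixed genetic-width (centimorgan) query windows
    around lead SNPs, and a synthetic-data generator with known ground
    truth for calibration and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
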