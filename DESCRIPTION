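Package: t6aribo
Title: Codon-Resolved Ribosome Occupancy, Footprint Simulation, and
    t6A-Related Translation Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the translational consequences of losing the
    t6A tRNA modification. Implements a codon-resolved ribosome-profiling
    pipeline in transcriptome space (read-length filtering, P-site offset
    calibration from the start-codon meta-profile, reading-frame selection,
    E/P/A-site and flanking-codon resolution, and a codon occupancy ratio
    normalised to downstream flanking codons), per-gene ribosome-stalling
    fold changes with rank-based gene-set comparisons, and a seeded
    footprint simulator with codon-dependent A-site dwell weights that
    provides ground truth for parameter-recovery testing. Auxiliary
    summaries cover tRNA isodecoder percentages and anticodon-group
    differential binding from RIP-seq counts, spatial-transcriptomics
    spot quality control with T-cell-proximity statistics, the flow
    cytometry aggregation propensity factor, and differential-expression
    signature selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    Matrix,
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
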