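Package: stallscan
Title: Codon-Resolved Detection of Ribosome Stalling from Ribo-Seq Footprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects codon-resolved ribosome stalling from ribosome profiling
    (Ribo-seq) libraries. Assigns ribosome-protected fragments to genes and
    reading frames, computes per-codon subsequence shifts between condition
    and control samples after gene-level normalization, tests amino-acid-level
    differences with a linear mixed model, builds normalized and smoothed
    footprint density profiles over 61-nt windows around codons of interest,
    and assesses significance of in-frame signals against an out-of-frame
    (+/- 1 nt) background with a two-tailed Z-test. Includes a synthetic
    footprint simulator with configurable per-codon dwell times that provides
    ground truth for every stage, plus a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    rtracklayer,
    Rsamtools,
    GenomicRanges,
    IRanges,
    lme4,
    lmerTest,
    nortest,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
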