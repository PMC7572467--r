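Package: tfbsnv
Title: Gain and Loss of Transcription Factor Binding Sites from Single-Nucleotide Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether single-nucleotide variants create or disrupt
    transcription factor binding sites by scoring reference and alternate
    alleles against position weight matrices with p-value calibrated score
    thresholds, and summarizes the effects as four per-TF probabilities
    (gainability, disruptability, hitability, robustness). Includes
    spectrum-matched random baselines, delta-score profiling of variant
    cohorts with empirical significance, complete-linkage clustering of
    per-sample profiles, and a fully synthetic fixture generator (genomes,
    motifs, planted sites, variant sets) so every step is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    vcfR,
    ape,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
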