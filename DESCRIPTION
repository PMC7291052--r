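Package: mazfkit
Title: Cleavage-Site Mapping, Kinetics and Target Prediction for the
    MazF Endoribonuclease of Nitrospira
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for characterizing the sequence specificity of
    the MazF-nd1 endoribonucleolytic toxin of Nitrospira strain ND1 and
    predicting its intracellular targets. Calls candidate cleavage sites from
    5'-end-capture coverage profiles via the relative-coverage-increase
    statistic, summarizes flanking sequences as position-frequency matrices
    with per-column information content, fits fluorometric cleavage time
    courses to the integrated first-order rate equation to rank recognition
    motifs by initial reaction velocity, and scans coding sequences with a
    binomial motif statistic to rank MazF-sensitive genes and extract
    MazF-tolerant ones. Seeded synthetic-data generators provide coverage
    profiles, fluorescence traces and CDS sets with known ground truth so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
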