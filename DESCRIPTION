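Package: screenpulse
Title: Temporally Resolved Pooled CRISPR Screen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of time-course pooled CRISPR knockout screens:
    non-targeting-control median-ratio normalization of sgRNA counts,
    negative-binomial maximum-likelihood gene beta-scores per condition and
    timepoint, differential beta-scores between drug and vehicle arms,
    mean +/- 2 sigma per-timepoint hit calling with a two-of-three-timepoint
    high-fidelity filter, Ward clustering of hit trajectories, and tiling
    (domain-scanning) screen analysis with control-normalized per-sgRNA
    survival rates and domain-as-gene beta-scores. Includes a seeded
    negative-binomial screen simulator with ground truth for parameter
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
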