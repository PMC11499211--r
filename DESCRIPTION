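Package: ethonet
Title: Behavioral Transition Network Analysis of Rodent Maternal Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing scan-sampled ethogram sequences of rodent
    maternal behavior as directed weighted transition networks. Reads and
    validates long-format observation tables, simulates observation datasets
    from seeded phase- and group-dependent Markov chains with a tunable
    fragmentation parameter, builds per-day group-averaged behavior networks,
    computes in-strength, out-strength and betweenness centrality with
    per-network z-standardization, and reproduces frequency-level group
    statistics (mean +/- SEM profiles, two-way mixed repeated-measures ANOVA
    with Sidak post hoc comparisons). Includes a reproducible pipeline with
    TSV exports, heat maps and network plots, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
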