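Package: scpairs
Title: Synthetic-Cytotoxicity Pair Screening from Mutation and Drug-Response Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers synthetic-cytotoxicity (SC) gene pairs from cancer
    cell-line cohorts: builds a binary sample-by-gene disruption matrix from
    annotated variant and copy-number tables (intolerant missense, loss of
    function, homozygous deletion), screens all gene pairs for jointly
    disrupted groups with significantly lower natural-log IC50 by one-sided
    rank-sum tests, summarises per-sample SC burden with Kruskal-Wallis and
    cross-drug comparisons, assembles the SC interaction network with Louvain
    communities, and validates pairs in patient cohorts with Firth-penalized
    Cox proportional-hazards regression and Kaplan-Meier curves. Includes
    seed-deterministic synthetic cell-line and patient cohort generators with
    known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
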