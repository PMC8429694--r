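Package: dnmpleio
Title: Genic and Allelic Pleiotropy Analysis of De Novo Coding Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical framework for testing whether rare coding de novo
    variants shared between trio cohorts of different disorders reflect
    genic pleiotropy (shared risk genes with congruent mutation classes) or
    allelic pleiotropy (identical risk alleles). Implements a trinucleotide
    mutation-rate null model for expected de novo counts, one- and
    two-sample exact Poisson rate-ratio tests, a class-congruence test on
    the difference of log rate ratios, genome-wide offset-Poisson
    regression of per-gene de novo counts on gene-level association
    statistics, and a Firth penalised-likelihood logistic regression for
    case-control burden replication. A seeded synthetic-cohort generator
    emulates gene, variant and case-control inputs so every statistical
    claim is checkable as parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
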