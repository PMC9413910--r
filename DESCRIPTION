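Package: ubcs
Title: Unexpected Biased Clustered Substitutions for Divergence and
    Fusion-Time Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and counts locally over-represented weak-to-strong
    (AT to GC) substitutions between aligned genomes and computes the
    UBCS statistic: the difference between the observed number of biased
    clustered substitutions in each 1 Mb region and its exact expectation
    under a null of independent bias labels.  The expectation is obtained
    by an exact dynamic program over a compressed bin representation of
    all candidate 300 bp windows around each substitution.  Downstream
    estimators derive relative divergence times between species pairs
    from telomeric UBCS proportions with bootstrap confidence intervals,
    and date the human chromosome 2 fusion from the decline of UBCS
    accumulation at the fusion site relative to control telomeres.
    Includes a synthetic-data generator emulating clustered, telomere-
    enriched, GC-biased substitution processes so that every stage of the
    pipeline can be exercised without whole-genome alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
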