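Package: endosig
Title: Cross-Study Gene Signatures for Chronic Inhaled Endotoxin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates independent murine lung expression studies of
    repeated inhaled endotoxin (lipopolysaccharide) exposure into a shared
    differential-expression gene signature. Provides permutation-based SAM
    differential expression with fudge-factor estimation and delta selection
    at a target false discovery rate, probe-to-gene harmonization across
    platforms, exact two-way and three-way hypergeometric tests for the
    significance of multi-study signature overlap, hypergeometric pathway
    enrichment with enrichment-map export, and consensus-clustering
    validation of a signature against a random-signature null. A synthetic
    multi-study data generator with a planted shared signature makes every
    stage testable without microarray downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    limma,
    mclust,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
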