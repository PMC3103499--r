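Package: crmbattery
Title: Common Cis-Regulatory Module Discovery in Gene Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers statistically significant common cis-regulatory
    modules (CRMs) in gene batteries, i.e. sets of genes that are both
    coexpressed and pathway-coherent. Promoters are represented as
    position-sorted profiles of oriented transcription-factor binding
    sites with multiple alternative promoters per gene; common modules
    are found by breadth-first combination of common oriented sites
    under a support threshold with a half-to-double instance-length
    band, scored against a background gene set with the hypergeometric
    upper-tail p-value, and calibrated by a randomization procedure
    that maps battery size to a significance threshold. Significant
    modules are decomposed into candidate critical transcription
    factors. A seeded synthetic-data generator with planted modules
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
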