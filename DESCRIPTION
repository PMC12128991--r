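Package: plaqueclone
Title: Clonal Architecture of Atherosclerotic Plaques from Multi-Segment
    Somatic Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing the somatic clonal architecture of
    atherosclerotic plaques from multi-segment, deep whole-exome variant
    calls with a patient-matched buffy-coat reference. Implements the
    matched somatic filtering cascade (read support, variant allele
    frequency, base quality, buffy-coat exclusion, two-round concordance,
    germline removal, cross-patient recurrence exclusion), read-weighted
    pooling of sequencing rounds, conversion of variant allele frequencies
    to clonal cell frequencies with sex-chromosome handling, spatial clone
    mapping across one-dimensional plaque segments with physical-extent
    bounds, grouping of co-travelling mutations into putative clones, and
    screening of clonal hematopoiesis (CHIP) mutations in blood with
    force-calling and quantification of their infiltration into plaque
    tissue. A binomial read-count simulator with planted ground truth
    supports end-to-end validation of every stage.
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
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
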