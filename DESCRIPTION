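Package: exburden
Title: Rare-Variant Prioritization and Carrier-Collapsing Burden Tests for
    Case-Control Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A small-cohort case-control exome association pipeline: site
    quality control by per-sample sequencing depth and an exact test of
    Hardy-Weinberg equilibrium, minor-allele-frequency stratification,
    classification of damaging variants from consequence and SIFT/PolyPhen2
    annotations, case-only candidate filtering, per-gene carrier-collapsing
    one-sided Fisher burden tests, single-variant association under five
    genetic models (trend, allelic, dominant, recessive, genotypic),
    mask-based gene-wise collapsing tests with Manhattan-plot export, and
    verification of a candidate-variant panel in an independent cohort.
    Includes a synthetic cohort generator with a planted ground truth so
    every stage is testable without access to protected sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
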