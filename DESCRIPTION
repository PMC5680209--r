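Package: panelvaf
Title: Low Allele Fraction Variant Detection and Limit-of-Detection
    Calibration for Targeted Cancer Panels
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational core of deep targeted-panel
    sequencing of clinical cancer samples: simulation of deduplicated
    panel pileups with tumor purity and subclonal structure, a
    binomial-error reference model for calling somatic single nucleotide
    variants at low variant allele fraction (VAF), panel-of-normals and
    regression-based artifact filtering, in silico dilution assays with
    probit regression to calibrate the limit of detection (the depth at
    which a given VAF is detected with 95% sensitivity), tumor purity
    inference from clustered SNP allele fractions, purity-adjusted
    exon-level copy number calling, split-read gene fusion calling, and
    digital PCR Poisson quantification with panel-vs-dPCR concordance
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    glmnet,
    jsonlite,
    pROC,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    knitr
Config/testthat/edition: 3
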