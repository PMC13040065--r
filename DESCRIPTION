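Package: fbgrowth
Title: Normative Fetal Brain Growth Standards and Maturation Index from
    3D Segmentation Label Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of second-trimester fetal brain growth from
    3D segmentation label volumes. Extracts 28 image-derived phenotypes
    (structure volumes, cortical surface area, distance-transform cortical
    depth, gradient-projection cortical thickness, lobe summaries and Sylvian
    fissure depth), fits fractional-polynomial normative growth standards with
    a log-linear standard-deviation model and centile/z-score evaluation,
    quantifies cross-site poolability (standardised site differences in
    3-week gestational windows and random-intercept variance components), and
    builds a deconfounded random-forest fetal brain maturation index with
    grouped cross-validation. Includes a synthetic-data module (cohort
    exclusion cascades, nested spherical label phantoms anchored to the
    published total-brain-volume growth equation, and simulated phenotype
    tables with configurable site, sex and hemisphere confounds) so the whole
    pipeline is testable without access-restricted scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    lme4,
    ranger,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    ggplot2
VignetteBuilder: knitr
Config/testthat/edition: 3
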