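Package: tibialCT
Title: Volumetric Tibial Bone-Defect Analysis from Periprosthetic CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tibial bone defects around implanted knee prostheses
    from computed-tomography volumes. Segments CT volumes into defect, bone,
    cement and implant classes by Hounsfield-unit thresholds, partitions the
    proximal tibia into epiphyseal, metaphyseal and diaphyseal fixation zones
    by the rule of the square, computes per-zone defect volumes and
    remaining-bone ratios, grades defects on the AORI ordinal scale, and
    provides the agreement statistics used to compare grading methods
    (Cohen's kappa with Landis-Koch interpretation, tie-corrected Spearman
    correlation, Friedman and Kruskal-Wallis tests, and Fisher-z power
    analysis). Includes a digital phantom generator that synthesizes
    periprosthetic tibial CT volumes with exact voxel-level ground truth, and
    a cohort simulator for ordinal grading agreement studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
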