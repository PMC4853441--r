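Package: fluencymap
Title: Voxel-Based Lesion-Symptom Mapping of Semantic and Phonemic Fluency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for voxel-based lesion-symptom mapping (VLSM)
    of verbal fluency in stroke cohorts: fluency scoring and demographic
    z-adjustment, mass-univariate voxel statistics (pooled-variance t and
    Brunner-Munzel) with Benjamini-Hochberg false-discovery-rate control,
    dichotomized lesion overlay and subtraction maps, atlas-based
    region-of-interest reports and regional infarct-volume regressions, and a
    fully deterministic synthetic lesion-cohort generator with ground truth so
    every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
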