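Package: vulm
Title: Volumetric Ultrasound Localization Microscopy of Cerebral Microvasculature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for volumetric (3-D + time)
    ultrasound localization microscopy (ULM) of the mouse brain: singular value
    decomposition clutter filtering on batches of beamformed intensity volumes,
    multi-stage subvoxel microbubble localization, Hungarian-assignment particle
    tracking with Savitzky-Golay trajectory smoothing and velocity estimation,
    super-resolution density and velocity rendering, and three vascular
    biomarkers (vascular dropout via 3-D skeleton centerline density, bilateral
    symmetry via mirror dice scoring, and localized hemodynamic reduction via
    spherical-shell speed profiles). Includes a synthetic 3-D vasculature and
    microbubble transit simulator so the whole chain is testable without
    acquisition hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    withr
Config/testthat/edition: 3
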