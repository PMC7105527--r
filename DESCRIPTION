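Package: pibflow
Title: Early-Phase Amyloid PET Perfusion, SUVr, fALFF and Group Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multimodal quantification pipeline for simultaneous amyloid
    PET/MRI studies of dementia. Estimates cerebral blood flow from the
    early phase of dynamic [11C]PiB PET using an image-derived arterial
    input function (hottest intracarotid voxels), single-exponential
    dispersion correction, and voxelwise one-tissue-compartment K1
    estimation by the three-weighted-integral method; computes SUV and
    cerebellar-reference SUVr images from late static frames, together
    with the gray/white-matter SUVr contrast ratio; derives ALFF/fALFF
    and subject-level z-score maps from resting-state fMRI series; and
    provides regional summaries over a parcellation, atrophy-style
    z-scores, group comparisons, and voxelwise two-sample t-maps with
    cluster-extent thresholding. Includes a synthetic digital phantom
    with known ground truth (gamma-variate arterial input, dispersed
    blood curves, one-tissue-compartment tissue kinetics, BOLD-like
    series) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    ggplot2,
    rlang,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse
Config/testthat/edition: 3
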