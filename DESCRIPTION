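Package: cleftvol
Title: Volumetric Assessment of Secondary Alveolar Bone Grafting from CBCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A standardized three-dimensional workflow for pre-operative
    planning and post-operative evaluation of secondary alveolar bone
    grafting in unilateral cleft patients from cone-beam computed
    tomography (CBCT). Reads DICOM series and NIfTI volumes, segments
    dense maxillary bone-plus-teeth models by dual thresholding with
    morphological gap filling, normalizes head orientation to the
    occlusal plane, mirrors the unaffected hemimaxilla across the
    mid-sagittal plane, rigidly registers binary models by maximizing
    their Dice overlap, and derives cleft, graft, integrated-bone,
    resorption and missing volumes plus filling, restoration and
    resorption rates by exact voxel Boolean algebra. Includes a
    synthetic maxilla phantom generator with exact ground truth for
    validation, STL surface export, and cohort summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
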