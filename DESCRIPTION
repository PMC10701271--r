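Package: doseloop
Title: Closed-Loop Automated Planning for Intracranial Stereotactic
    Radiosurgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A closed-loop automated treatment-planning pipeline for
    single-lesion brain stereotactic radiosurgery (SRS). Generates
    synthetic head phantoms (CT, target and organ-at-risk contours, and a
    physically consistent reference dose), preprocesses cases into
    normalized tensors, predicts 3D dose distributions with 3D UNet and
    attention-fusion UNet (AttUNet) models implemented natively in R,
    converts a predicted dose into a deliverable plan by deposition-matrix
    fluence mimicking with auto-configured coplanar beams and dual-layer
    orthogonal MLC sequencing, and verifies plans with a full dosimetric
    metric suite (DVH, conformity and homogeneity indices, dose spillage,
    and 2D/3D gamma analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
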