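Package: vromm
Title: Videogrammetric Reconstruction of Skeletal Kinematics and Muscle
    Strain from External Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for marker-based videogrammetry of feeding and locomotor
    behaviour in fishes: direct linear transformation (DLT) camera
    calibration and multi-view triangulation, rigid-body and body-plane
    pose estimation, anatomical and joint coordinate system kinematics
    (retraction, depression, neurocranial elevation), muscle strain and
    shortening-velocity estimation from skin-mounted marker pairs, and
    the validation statistics used to compare external marker tracking
    against implanted-marker reference methods. A synthetic suction-strike
    generator provides ground truth for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
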