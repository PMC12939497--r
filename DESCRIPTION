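Package: mpflopt
Title: Motion-Informed Femoral Attachment Localization for MPFL Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies a patient-specific femoral attachment point for medial
    patellofemoral ligament (MPFL) reconstruction from time-resolved (4D-CT)
    knee motion. Given per-frame femoral and patellar surfaces and anatomical
    landmarks, the package builds a femur-centered coordinate system, tracks
    the patellar articular centroid across flexion, and solves a constrained
    sequential quadratic program that minimizes the variance of the modeled
    ligament length over the motion, subject to the candidate point lying on
    the femoral surface within a 5-15 mm annulus around the radiographic
    Schottle point. Includes graft length-change (MPFL%) profiling per
    flexion angle, cohort statistics (PERMANOVA, exact paired Wilcoxon
    signed-rank, axis variance partitioning, classical MDS and kernel
    densities), a synthetic joint-motion simulator with planted isometric
    optima for validation, and mesh/manifest/landmark file IO.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    quadprog,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse,
    yaml
Config/testthat/edition: 3
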