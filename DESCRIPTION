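Package: prmstrain
Title: Strain Imaging of the Puborectal Muscle from Dynamic 3D Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify contraction of the puborectal muscle (PRM)
    from dynamic 3D transperineal ultrasound. The pipeline tracks
    inter-volume speckle motion by normalized cross-correlation block
    matching, accumulates displacements Lagrangianly, extracts the muscle
    centerline as a proxy for the fiber direction, projects displacements
    onto the local tangent, estimates fiber-direction strain with a 2x2x2
    least-squares strain estimator, and summarizes strain medians in the
    two end regions and the mid region of the muscle sling. A normalized
    strain ratio contrasts the two ends and separates intact muscles from
    muscles with unilateral avulsion; cohorts are compared with an exact
    Mann-Whitney U test. Includes a seeded synthetic speckle-phantom
    generator with analytically known displacement and strain fields for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
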