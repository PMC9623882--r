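Package: stereoslant
Title: Gaze-Invariant Recognition of 3D Planar Orientation from Vergent
    Binocular Disparity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates an actively fixating binocular head (toe-in vergent
    geometry, Helmholtz eye kinematics, optional binocular Listing torsion),
    renders random-dot stereo pairs of slanted/tilted planes with ground-truth
    vector disparity fields, encodes them in a population of binocular-energy
    complex cells, computes distributed first-order disparity-field
    differentials (divergence, rotation, and the two deformation components),
    and trains a recurrent gaze-block network with backpropagation through
    time to classify head-centric surface orientation into nine slant/tilt
    classes.  Includes an active next-gaze selection loop, a robustness sweep
    that smooths the disparity input, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
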