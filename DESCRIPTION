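Package: bvrkin
Title: Synthetic Validation of Model-Based Biplane Videoradiography Knee Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the accuracy, bias, and precision of
    model-based biplane videoradiography (BVR) tracking of tibiofemoral
    kinematics against a marker-based gold standard. Provides rigid-transform
    and quaternion algebra, Kabsch point-set registration, a synthetic BVR
    scene generator (calibrated two-view X-ray geometry, frozen cadaveric
    femur-tibia specimens carrying implanted beads, hop and drop landing
    trajectories, per-frame bead projections, and a noise-model emulator of
    model-based 2D-3D registration), biplane triangulation and marker-based
    pose reconstruction, quaternion-filtered six-degree-of-freedom joint
    kinematics with X-Y-Z Euler decomposition, and Bland-Altman agreement
    statistics (mean absolute difference, bias, limits of agreement with
    confidence intervals) stratified by bone, specimen, and motion type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
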