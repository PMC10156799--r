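Package: fontanflow
Title: 4D Flow MRI Hemodynamics of the Total Cavopulmonary Connection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative hemodynamics for 4D flow MRI of the Fontan
    circulation (total cavopulmonary connection). Provides synthetic 4D flow
    phantoms with analytic ground truth (uniform flow, Poiseuille tube,
    solid-body rotation, and a streamfunction-based caval junction with an
    exact flow split), phase-contrast preprocessing (phase-offset correction,
    velocity anti-aliasing, noise masking, PC-MRA), vessel centerlines and
    region partitioning, pathline particle tracing with caval flow
    distribution, voxel-wise hemodynamic maps (peak velocity, stasis,
    kinetic energy, viscous energy loss), and the longitudinal nonparametric
    statistics used to follow these metrics over time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
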