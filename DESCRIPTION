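Package: eit3d
Title: Three-Dimensional Electrical Impedance Tomography with Neural Post-Processing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and reconstruction toolkit for difference electrical
    impedance tomography (EIT) in two and three dimensions. Builds finite
    element models of cylindrical saline tanks and thorax-like contours with
    complete-electrode-model boundary conditions, defines adjacent
    stimulation/measurement protocols, solves the forward problem and its
    adjoint sensitivity (Jacobian), and reconstructs conductivity changes
    with a one-step Gauss-Newton solver (NOSER prior), a primal-dual interior
    point solver (L1 data norm, L2 regularisation), and radial basis function
    networks used either as a direct inverse solver or as a nonlinear
    post-processor of the linear reconstruction. Includes a carrier-level
    measurement noise simulator with per-channel SNR calibration and
    GREIT-style figures of merit (position error, resolution difference,
    shape deformation) on rasterised cross-sections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
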