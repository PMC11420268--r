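Package: laaoflow
Title: Desk-Scale Hemodynamics of Left Atrial Appendage Occlusion Devices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric left atrium / left atrial appendage (LAA) geometry
    generation, virtual implantation of plug-style (non-pacifier) and
    disc-style (pacifier) appendage occluders, pulsatile incompressible flow
    simulation under atrial-fibrillation inflow, passive "old blood" washout,
    and the surrogate markers of device-related thrombus risk: residual blood
    fraction, washout half-time, time-averaged wall shear stress (TAWSS),
    oscillatory shear index (OSI) and endothelial cell activation potential
    (ECAP), with the standard adhesion (0.36 Pa) and activation (1.4 1/Pa)
    thresholds. Includes analytic channel-flow benchmarks (Poiseuille,
    oscillatory Womersley) for solver validation and a nine-scenario
    comparative study of device type and implant position.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
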