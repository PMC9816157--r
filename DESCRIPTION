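Package: quadrelax
Title: Quadrupolar NMR Relaxation from Electric Field Gradient Fluctuations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing quadrupolar NMR relaxation rates of spin > 1/2
    nuclei (such as 23Na) from point-charge particle configurations of periodic
    simulation boxes. Provides Ewald-summed electric field gradient (EFG)
    tensors at ion sites, Sternheimer calibration of the electron-cloud
    enhancement against ab initio EFG tables, tensor autocorrelation and
    effective correlation-time analysis with exponential and stretched
    (Kohlrausch) fits, the spin-3/2 extreme-narrowing rate formula, and the
    accompanying transport analysis: Green-Kubo shear viscosity, mean-squared
    displacement diffusion with the Yeh-Hummer finite-size correction,
    Stokes-Einstein-Debye model assessment, water dipole reorientation times,
    and structural relaxation times from stress autocorrelation functions.
    Seed-deterministic synthetic-data generators with known ground truth
    (Langevin ionic fluids, prescribed-ACF tensor processes, Maxwell-mode
    stress, Brownian walkers and rotors) exercise the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
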