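Package: smfsim
Title: Particle-Based Simulation of Membrane Protein Dynamics for
    Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("smfsim", "developers", email = "smfsim@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo engine for single-molecule membrane protein
    dynamics in 2D cell geometries: Brownian diffusion with
    region-dependent coefficients, reversible diffusional trapping at
    adhesive contacts, probabilistic border crossing, and fluorophore
    photophysics (blinking, photoactivation, photobleaching).  Produces
    synthetic data for single particle tracking (SPT/uPAINT),
    single-molecule localization microscopy (dSTORM/PALM), FRAP, PAF and
    FCS, together with the matching analysis pipelines: MSD-based
    diffusion estimation, super-resolved map accumulation, recovery and
    decay curve normalization, and intensity autocorrelation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
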