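Package: smfretsim
Title: Stochastic Simulation of Single-Molecule FRET with Dye Linker and
    Dipole Orientational Dynamics
Version: 0.1.0
Authors@R:
    person("smfretsim", "developers", email = "smfretsim@example.org",
           role = c("aut", "cre"))
Description: Simulates time-resolved confocal single-molecule FRET (smFRET)
    experiments in which the translational motion of the fluorescent dyes
    (Ornstein-Uhlenbeck springs parameterized by C-C linker chemistry, or a
    stochastic elastic pendulum) and the orientation of their transition
    dipoles (spherical Brownian motion) drive a time-inhomogeneous
    continuous-time Markov chain of photon emission. Provides closed-form
    FRET mathematics (orientation factor, transfer rates, intensity and
    lifetime efficiency estimators, Jensen's-inequality lifetime bounds),
    burst-level photon sampling with detection losses, and quantification of
    the dynamic shift of the joint FRET-efficiency/donor-lifetime
    distribution, including a two-state mixing reference model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
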