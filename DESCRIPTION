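Package: inertabp
Title: Underdamped Active Brownian Motion: Simulation, Theory and Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the underdamped (inertial) Langevin model of active
    Brownian motion, the standard description of macroscopic self-propelled
    particles such as vibrationally driven granular robots ("vibrobots"),
    where mass and moment of inertia can no longer be neglected.  Provides an
    exact-transition stochastic simulator for the coupled translational and
    rotational Ornstein-Uhlenbeck dynamics, closed-form evaluation of the
    orientational correlation, short- and long-time mean squared
    displacements, the long-time diffusion coefficient and its small- and
    large-inertia asymptotics, the analytic orientation-velocity delay
    function (via the lower incomplete gamma function of complex argument),
    stationary velocity distributions, empirical trajectory estimators with
    ensemble error bands, and a staged plus simplex parameter-inference
    scheme that recovers the six identifiable model rates from trajectory
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    pracma,
    minpack.lm
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
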