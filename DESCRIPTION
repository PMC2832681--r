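Package: hekf
Title: Constrained Hybrid Extended Kalman Filtering and Chi-Squared
    Validation for ODE Models
Version: 0.1.0
Authors@R:
    person("hekf", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint state and parameter estimation for ordinary differential
    equation models of biochemical systems from noisy, sparse, possibly
    non-uniformly sampled measurements. Implements a constrained hybrid
    extended Kalman filter (continuous-time prediction through the model ODE
    and a differential Lyapunov equation, discrete-time measurement
    correction, and quadratic-programming projection onto linear
    constraints), an a posteriori chi-squared variance test that accepts or
    rejects an estimate against known measurement-noise statistics, a
    moment-matching refinement stage for estimates that fail the test, and a
    chi-squared model-selection procedure for discriminating among candidate
    models. Ships fixture models (an E. coli heat-shock response model, a
    no-spike variant, and a generalized repressilator) together with a
    synthetic-measurement generator, a CSV/JSON measurement and report
    format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    quadprog,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
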