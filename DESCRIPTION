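Package: ratabolic
Title: Energy-Balance Modelling of Rat Body Weight and Body Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modelling short-term body-weight and body-composition
    dynamics in laboratory rats from daily food-intake records. Implements a
    two-compartment (fat mass / fat-free mass) energy-partition ODE model with
    a closed-form energy-expenditure function and Hill-type drug effect, and a
    derived "alpha-free" model that infers body-composition change from body
    weight and intake alone via a smoothing-spline body-weight input.
    Calibration machinery covers Kleiber allometric translation of metabolic
    rates, total-least-squares estimation of the energy-partition slope,
    scalar fitting of the physical-activity coefficient, simulated-annealing
    estimation of drug-effect parameters, and identifiability error surfaces.
    A synthetic-study generator emulates caloric-restriction and CB1-receptor
    antagonist study designs for end-to-end testing and parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr
Config/testthat/edition: 3
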