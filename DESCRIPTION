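Package: bmisim
Title: Individual-Level Micro-Simulation of Childhood BMI Trajectories
Version: 0.1.0
Authors@R: person("bmisim", "maintainers", email = "maintainers@bmisim.org",
    role = c("aut", "cre"))
Description: Discrete-time, individual-level simulation of body-mass index
    (BMI) trajectories from early childhood (ages 4/5) to adolescence (ages
    14/15). Includes a calibrated synthetic longitudinal cohort generator,
    BMI-for-age z-score classification via the LMS method, sex-stratified
    piecewise-linear annual BMI-change equations fitted by weighted least
    squares, life-table mortality, survey-weighted estimation of means and
    prevalences with Taylor-linearized variance, an intervention-effect
    overlay, and a health-economic layer (QALYs, costs, discounting, ICERs)
    for evaluating childhood obesity prevention programmes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
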