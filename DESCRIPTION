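Package: senodyn
Title: Dynamical Modelling of the Transition to Replicative Senescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Age-structured compartmental ODE model of a proliferating cell
    culture's transition to replicative senescence. Proliferative cells are
    stratified by doubling age with linearly age-dependent rates of division
    and of transition into senescent, growth-arrested and apoptotic states.
    Includes mapping of population trajectories onto five experimental
    readouts (population doublings, SA-beta-Gal, Ki-67, gammaH2AX, TUNEL),
    a genetic-algorithm plus gradient-descent fitting engine, synthetic
    dataset generation emulating a 16-passage triplicate marker experiment,
    and downstream analyses: sparse measurement-design strategies, parameter
    sensitivity maps, holdout refitting, growth-arrest peak timing and
    time-to-senescence summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
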