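Package: raphenet
Title: Augmented Integrate-and-Fire Models and Network Simulations of the Dorsal Raphe
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and two-stage estimation of generalized integrate-and-fire
    (GIF) neuron models extended with Hodgkin-Huxley style A-type and steady-state
    potassium currents (aGIF) and a voltage-coupled dynamic threshold (iGIF), as
    used to model serotonin (5-HT) and somatostatin (SOM) neurons of the dorsal
    raphe nucleus. Includes spike-prediction metrics (spike-window-excluded R
    squared on dV/dt, the chance-corrected Md* coincidence score, intrinsic
    reliability), frozen Ornstein-Uhlenbeck stimulus and surrogate-recording
    generators, a feedforward-inhibition population network simulator with
    conductance-based GABA synapses, and time-resolved gain, divisive/subtractive
    inhibition and ramp derivative-encoding analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
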