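Package: rotorShEn
Title: Spiral-Wave Simulation and Shannon Entropy Mapping of Bipolar
    Electrograms
Version: 0.1.0
Authors@R:
    person("Workbench", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates spiral waves (rotors) in two-dimensional monodomain
    sheets of excitable tissue under FitzHugh-Nagumo, Luo-Rudy 1991
    ventricular and Courtemanche-Ramirez-Nattel atrial cell models,
    forward-models extracellular unipolar and bipolar electrograms,
    and maps the Shannon entropy of bipolar electrogram amplitude
    histograms across the sheet. Includes spiral-tip tracking via
    isoline intersection, wavefront propagation-direction analysis,
    Butterworth IIR filtering of electrograms, an analytic rigidly
    rotating geometric spiral model, and a configuration-driven
    experiment pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    yaml,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
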