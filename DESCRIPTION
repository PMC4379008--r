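Package: silentsub
Title: Receptor Silent Substitution and Melanopsin Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Design of receptor silent-substitution light stimuli from LED
    spectral power densities and visual-pigment templates, generation of
    melanopsin-isolating stimulation protocols (steady-background contrast
    steps, neutral-density irradiance ramps, calibration flicker, dark-adapted
    pulses), simulation of rod- and melanopsin-driven spike trains for coneless
    (Cnga3-/-) retina and dLGN preparations, and the matching spike-train
    analyses: responder classification, peri-stimulus rate estimation,
    1-SD response latencies, repeated-measures ANOVA with Bonferroni
    post-hocs, irradiance tracking and threshold-irradiance estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
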