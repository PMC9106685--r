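Package: stereomotion
Title: Image-Statistics Models of Motion-in-Depth Cue Integration
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the imaging statistics that link scene parameters
    (viewing distance, distance moved, surface size) to the two primary
    visual cues for motion-in-depth: changing binocular disparity (CD) and
    changing image size (CS). Monte Carlo simulations of rigid linear
    motions define binned joint posterior distributions p(v, m | CD) and
    p(v, m | CS) and the cue co-occurrence distribution p(CS and CD).
    These tables drive model observers for two-interval forced-choice
    speed-in-depth discrimination and cue-conflict detection, together
    with the psychometric analyses used to interrogate such observers:
    cumulative-Gaussian PSE/JND fitting, implied single-cue uncertainty
    under maximum-likelihood linear integration, and equivalent physical
    size ratios for threshold-level cue conflicts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
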