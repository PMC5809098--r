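Package: loopgain
Title: Neural Gain Modulation by Closed-Loop Environmental Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how closed-loop sensorimotor feedback reshapes
    neural dynamics. Implements a minimal open-loop/closed-loop/replay model of
    brain-environment interaction with its closed-form variance and gain
    predictions; a rate-based cortical network coupled to a two-segment vibrissa
    with spike-frequency adaptation, a stochastic whisking pattern generator,
    wall contacts and Chernoff-distance discriminability analysis; and a
    closed-loop system-identification pipeline that estimates afferent,
    efferent and round-trip feedback filters in Laguerre and Hermite bases from
    paired closed-loop/replay recordings, together with a synthetic session
    generator emulating fictive-swimming virtual-reality experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
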