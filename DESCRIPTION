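Package: mdrgait
Title: Micro-Doppler Radar Gait Analysis and Faller Classification
Version: 0.1.0
Authors@R:
    person("mdrgait", "maintainers", email = "mdrgait@example.org",
           role = c("aut", "cre"))
Description: Tools for fall-risk screening from continuous-wave micro-Doppler
    radar gait recordings. Provides a parametric simulator of complex-baseband
    radar returns from a walking subject (torso, toe and shank scattering
    centers), Butterworth high-pass clutter removal, short-time Fourier
    transform spectrograms with a Doppler-velocity axis, extraction of the
    upper, lower and power-weighted mean velocity envelopes, the four
    envelope-derived gait parameters used for faller screening, and a
    Gaussian-kernel soft-margin support vector machine with grid-search
    hyperparameter tuning for either accuracy or sensitivity. Includes a
    reproducible experiment runner and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
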