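Package: bcicodesign
Title: Joint Encoder-Decoder Design for Linear-Gaussian Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing matched encoder-decoder pairs for
    brain-computer interface cursor control under a linear-Gaussian model.
    Provides steady-state Kalman filter (SSKF) decoder solvers via the
    discrete algebraic Riccati equation, exact stationary mean-squared-error
    evaluation of arbitrary encoder-decoder pairs through augmented Lyapunov
    equations, and coordinate-wise joint optimization of the encoding matrix
    and the SSKF decoder under trace-of-quotient or SNR penalties on the
    neural signal power. A closed-loop online-prosthesis-simulator emulator
    with a simulated learning user supports end-to-end evaluation of
    pre-computed versus motor-imitation decoders on point-to-point reaching
    and pursuit-tracking tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
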