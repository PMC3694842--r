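Package: nfkbdde
Title: Delayed Dual Negative Feedback Models of the NF-kB Signaling Module
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reduced delay-differential-equation models of the IkBalpha/IkBeps
    negative feedback loops that control nuclear NF-kB, with Lambert-W linear
    stability analysis of the oscillatory response, damping optimization of the
    secondary feedback loop, duration-encoding analysis of pulsed stimulation,
    and exact stochastic simulation of the discrete reaction networks with
    delayed synthesis reactions (Gillespie algorithm with the Bratsun
    modification).  Includes generators for surrogate experimental observables
    (mRNA induction curves, noisy trajectories) and the half-maximal-delay
    estimation and parameter calibration procedures used to anchor the models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
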