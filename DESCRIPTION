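Package: msregistry
Title: Multi-State Life-Course Analysis of Welfare-Benefit Registry Episodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing life-course trajectories through employment,
    sickness and disability benefits, emigration and death recorded as
    episode-level registry extracts. Episodes are converted to a counting
    process with delayed entry and employment-gap filling; cumulative
    transition intensities are estimated by the Nelson-Aalen estimator with
    variances, transition probabilities by the Aalen-Johansen product-limit
    estimator, and state-occupation probabilities and restricted mean times
    in state are derived from them, with simulation-based confidence
    intervals obtained by perturbing the estimated intensity increments.
    Marginal discrete-time hazard models with a complementary log-log link
    are fitted by generalized estimating equations with an AR(1) working
    correlation and robust variances, producing hazard-rate-ratio tables by
    IQ and mental-health group before and after age 35. A seeded
    continuous-time Markov cohort generator emulating a national benefit
    registry observed through a fixed calendar window supports testing and
    calibration without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    Matrix
Config/testthat/edition: 3
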