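Package: bassadopt
Title: Bass Diffusion Modelling of Technology Adoption from Weighted Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating and forecasting consumer technology adoption
    with the Bass mixed-influence diffusion model, motivated by the uptake of
    personal health record (PHR) functionality measured in repeated weighted
    cross-sectional surveys. Provides weighted tabulation of two-item survey
    responses into joint-use adoption series, constrained nonlinear
    least-squares estimation of the innovation (p) and imitation (q)
    coefficients with start-date sensitivity analysis and leave-last-year-out
    stability checks, multi-scenario forecasting against policy milestone
    curves, and a seeded synthetic survey generator for end-to-end parameter
    recovery experiments.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    graphics,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
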