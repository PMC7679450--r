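Package: thermodepth
Title: Non-Contact Depth Temperature Profile Estimation from Surface
    Thermography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the subsurface temperature peak induced by
    hyperthermic laser treatments from an infrared recording of the surface
    temperature during thermal relaxation. Candidate depth temperature
    profiles from a parametric family are forward-simulated with a 1D
    heat-diffusion model under convective and radiative surface losses, and
    a measured surface trace is inverted by time-windowed matching against
    the simulated database, yielding the peak temperature and its depth
    together with windowed accuracy diagnostics. Includes a synthetic
    thermography generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
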