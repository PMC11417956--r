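Package: ctxgrowth
Title: Urinary CTX-I as a Non-Invasive Bone-Growth Marker: Simulation,
    Preprocessing and Hierarchical Skew-Normal Spline Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating urinary C-telopeptide of type I collagen
    (CTX-I) as a bone resorption marker against long-bone growth velocity in
    longitudinal primate data. Provides a synthetic cohort generator with
    configurable sex-specific growth-velocity and biomarker age curves,
    specific-gravity correction and quality filtering of urine samples,
    forearm growth-velocity derivation with midpoint velocity dates,
    day-to-day coefficient-of-variation descriptives, hierarchical Bayesian
    skew-normal regression with B-spline age smooths fitted by a built-in
    No-U-Turn sampler, Gelman-Rubin diagnostics and posterior predictive
    checks, and rank-correlation comparison of per-age-window spline
    estimates between the growth and biomarker models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    splines,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
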