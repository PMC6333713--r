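Package: mdmc
Title: Multimodal Diffusion Model for Conflict Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and fitting toolkit for the Multimodal Diffusion Model
    for Conflict Tasks (MDMC) and its faster-neutral variant (FN-MDMC). A
    controlled constant-drift diffusion process is superimposed with one or
    more pulse-like automatic activation processes (rescaled Gamma time
    course), one per task-irrelevant sensory modality, and the superimposed
    process is run to absorption at symmetric decision boundaries. The package
    generates trial-level two-choice conflict-task data (Simon-type designs),
    computes the standard distributional summaries (CDF quantiles, conditional
    accuracy functions, delta functions, marginal CDFs), and estimates model
    parameters by minimising a quantile/CAF-based G-squared discrepancy with a
    multi-start Nelder-Mead simplex over Monte-Carlo predictions, with BIC and
    paired-permutation model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
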