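Package: attrddm
Title: Attribute-Weighted Drift Diffusion Modeling of Normative Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits an attribute-weighted two-boundary drift
    diffusion model (DDM) of self-control dilemmas such as altruistic
    sacrifice and healthy eating. Evidence on each trial accumulates as a
    weighted sum of attribute differences (e.g. tastiness and healthiness,
    or payoffs for self and other) plus Gaussian noise until it reaches a
    response threshold, yielding choices, response times and a trial-wise
    neural-activity proxy (the summed absolute accumulated evidence).
    Provides grid simulation experiments over attribute differences and
    goal-weight contexts, simulation-based Bayesian parameter estimation by
    differential-evolution MCMC with Gelman-Rubin diagnostics, construction
    of model-predicted trial-by-trial neural regressors in fMRI
    design-matrix form, and synthetic behavioral data generators for both
    task families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
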