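Package: histddm
Title: History-Dependent Initial States in Evidence-Accumulation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modeling two-alternative choice behavior in pulsatile
    evidence-accumulation tasks with trial-history-dependent initial
    accumulator states. Implements exponential choice-outcome history filters,
    closed-form drift-diffusion choice probabilities, a Fokker-Planck
    likelihood engine for click-based accumulation with sensory adaptation and
    sticky bounds, true-lapse mixture models (motor error, inattention,
    hybrid), Wald non-decision-time distributions with a joint choice and
    reaction-time likelihood, four-parameter logistic psychometric fits with
    history-conditioned threshold and lapse-rate modulation metrics, maximum
    likelihood fitting with per-trial BIC model comparison, and a generator
    for fully synthetic behavioral sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    statmod,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
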