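Package: vseigt
Title: Value plus Sequential Exploration Modelling of Iowa Gambling Task Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reinforcement-learning models of trial-by-trial choice behavior in the
    Iowa Gambling Task, centered on the Value plus Sequential Exploration (VSE)
    architecture, which separates reward-driven exploitation, random exploration and
    recency-based directed exploration. Provides six competitor models (EV, PVL,
    PVL-Delta, VPP, ORL and a loss-averse VSE variant), maximum-a-posteriori fitting
    under flat-after-transform Gaussian priors with Laplace approximation of model
    evidence, fixed-effect and random-effects Bayesian model comparison with
    exceedance probabilities, model-free sequential-exploration metrics with analytic
    and permutation nulls, and full simulation, parameter-recovery and model-recovery
    pipelines with a canonical or empirically resampled payoff schedule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
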