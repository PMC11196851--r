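Package: ilcens
Title: Inverse Lindley Inference for Adaptive Type-I Progressively Censored Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Point and interval estimation for the one-parameter inverse
    Lindley lifetime model observed under adaptive Type-I progressive
    censoring. Provides the distribution functions, a censored-sample
    container with its removal algebra and a sequential sampler, and six
    estimators of the scale parameter and of the reliability and hazard
    functions: maximum likelihood, maximum product of spacings, Bayes under
    squared-error loss with a gamma prior using either the likelihood or the
    spacing function as the data source (via random-walk Metropolis-Hastings),
    and their E-Bayesian extensions that average the Bayes estimator over a
    beta x uniform hyperprior. Includes Wald and delta-method confidence
    intervals, equal-tailed credible intervals, gamma-prior elicitation from
    pilot samples, Kolmogorov-Smirnov goodness of fit with information
    criteria, and a Monte-Carlo evaluation harness reporting average
    estimates, RMSE, mean absolute bias and average interval lengths.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
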