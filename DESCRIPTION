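Package: avdistci
Title: Bayesian Causal Inference Models of Audiovisual Distance Perception
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Non-generative Bayesian causal-inference analysis of audiovisual
    distance perception. Implements closed-form multisensory model predictors
    (maximum-likelihood cue integration, segregation, and three strategies for
    resolving an uncertain causal structure: model selection, model averaging,
    and probability matching), three rival models without causal inference
    (sensory dominance, mandatory integration, no interaction), a sensory-weight
    calculus with interaction-window quantification, discretized
    response-distribution predictions scored by ordinary-least-squares
    goodness of fit, and a synthetic observer that generates trial-level
    psychophysical response tables with the statistical structure the analysis
    assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
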