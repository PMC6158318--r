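Package: activevision
Title: Active Inference for Saccadic Scene Construction with Inferred Sensory Precision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-state active inference for visual foraging. Implements
    variational belief updating over a Markov decision process generative model
    with a precision-modulated likelihood, online inference of sensory precision
    (gain) under Gamma beliefs, expected-free-energy saccade selection, and a
    two-level hierarchical model of visual scene construction with descending
    empirical priors and ascending evidence. Includes the four-location visual
    foraging task, simulated lesions of high-level scene priors (a computational
    account of false perceptual inference), scenario runners for healthy and
    pathological perception, tidy trial records, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
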