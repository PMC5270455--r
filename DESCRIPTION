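Package: timdyn
Title: Dynamic Boolean and Markov Models from Target Inhibition Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers dynamic models of tumor proliferation circuits from
    steady-state drug-perturbation response maps. A target inhibition map
    (TIM) records, for every combination of inhibitable kinase targets,
    whether joint inhibition blocks tumor proliferation; its probabilistic
    extension (PTIM) records a normalized sensitivity in [0,1]. The package
    reconstructs series-parallel directional pathways consistent with a TIM,
    converts them to deterministic Boolean networks under target-inhibition
    masking, derives closed-form bounds and a simulator for the number of
    steady-state expression experiments needed to orient a pathway, builds
    Markov chains and context-sensitive probabilistic Boolean networks whose
    steady-state inhibition profiles reproduce the input PTIM, and evaluates
    sustained and periodic (sequential) drug regimens on the fitted models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
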