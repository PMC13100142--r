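Package: biruni
Title: Al-Biruni Earth Radius Optimization, Wrapper Feature Selection and
    Gated Sequence Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Al-Biruni Earth Radius (BER) population
    metaheuristic with dynamically rebalanced exploration and exploitation
    groups, elitism and stagnation-triggered mutation; a binary variant for
    wrapper feature selection over deep-feature tables with a binary particle
    swarm control; a long short-term memory (LSTM) classifier built from the
    gate equations together with a multilayer perceptron baseline and
    BER-driven hyperparameter tuning; classification metrics with Wald
    confidence intervals, balanced accuracy, exact Wilcoxon signed-rank and
    one-way ANOVA model comparison; and seeded synthetic benchmark objectives
    and two-class feature-table generators so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    class,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
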