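Package: freqnet
Title: Frequency Nets and Exact Analysis of Two-Event Probability Situations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with probabilistic situations involving two
    dichotomous events, as they arise in Bayesian reasoning tasks and in
    teaching diagnostic-test statistics (base rate, sensitivity,
    false-positive rate, positive predictive value). Completes all sixteen
    probabilities of a situation exactly from any determining subset of
    marginal, joint and conditional probabilities or absolute frequencies,
    using exact rational arithmetic; validates assignments against the four
    net rules (line, triangle, V and X rules); converts between probabilities
    and natural frequencies; builds 2x2 tables, tree diagrams, double-trees
    and frequency-net diagrams as explicit node/edge structures rendered to
    monospaced text or SVG; encodes the catalogue of correct and erroneous
    Bayesian answer strategies, predicts each strategy's answer, classifies
    numeric responses and applies study-style correctness coding; and ships
    the mammography and economics task bank with a balanced design generator
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
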