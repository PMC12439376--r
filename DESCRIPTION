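Package: fptree
Title: Fuzzy Probability Trees for Interpretable Clinical Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Discrete probability trees induced from tabular clinical records,
    extended with fuzzy linguistic variables so that prediction traverses all
    matching branches weighted by membership degrees. Provides an event algebra
    over tree realizations, what-if (counterfactual) scenario queries, a
    bootstrap evaluation harness with stratified splitting and percentile
    confidence intervals, synthetic cohort generators with known generating
    rules, JSON model serialization, GraphViz DOT export, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
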