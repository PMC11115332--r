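Package: fuzzrisk
Title: Fuzzy FMEA and Hybrid Multi-Criteria Risk Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Risk assessment for expert-elicited failure-mode registers under
    linguistic uncertainty. Provides triangular fuzzy number (TFN) arithmetic,
    linguistic rating scales for Occurrence, Severity and Detection, the
    multiplicative fuzzy risk priority number (F-RPN), a Mamdani max-min fuzzy
    inference engine with centroid defuzzification, three fuzzy multi-criteria
    rankers (fuzzy ARAS, fuzzy VIKOR, fuzzy WASPAS), and a hybrid aggregation
    that merges the per-method benefit indices into an ultimate utility index
    via Euclidean distances to positive and negative ideal index vectors.
    Includes a seeded synthetic risk-register generator, rank-agreement
    metrics, packaged worked-example fixtures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
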