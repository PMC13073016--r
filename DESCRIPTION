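Package: haemoscore
Title: Delphi-Weighted Composite Monitoring Score for Haemophilia A and B
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a consensus-based monitoring tool for haemophilia A and
    B in prophylactic and on-demand treatment settings. Ships four published
    instrument configurations with expert-derived domain and item weights,
    computes a hierarchical weighted composite score on a 0-100 scale with four
    interpretive categories, derives the raw clinical measures the items are
    built on (annualised bleeding rates, adherence percentage, EQ-5D-5L level
    sum score) and buckets them into the instrument's answer bands, and
    provides the full two-round constant-sum Delphi analytics used to derive
    the weights (quartile summaries, interquartile-range consensus rule,
    round-two bound checks, median-based weight derivation) together with
    seeded synthetic generators for expert panels and patient cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
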