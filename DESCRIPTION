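Package: radex
Title: Rule-Based Information Extraction from Free-Text Clinical Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A rule-based data extraction toolkit for free-text clinical and
    radiology reports. Search strategies are written in a high-level query
    language of keywords, wildcard modifiers, proximity operators (NEAR/X,
    THEN/X) and boolean connectors, and are compiled into word-boundary-aware
    regular expressions. The package provides corpus filtering, header-based
    report sectioning, text standardisation with offset maps, NegEx-style
    negation detection, multi-label report classification with derived
    classes and post-processing rules, evidence highlighting for iterative
    strategy refinement, multi-label evaluation metrics (Hamming loss, exact
    match ratio, micro/macro averages, Cohen's kappa), and a seeded template
    generator of labelled synthetic thyroid ultrasound reports. A packaged
    search strategy classifies neck/thyroid ultrasound reports for fourteen
    clinical features including British Thyroid Association (BTA) nodule
    gradings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
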