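Package: twinpillars
Title: Twin Models and Regression Trees for Multiple Lifestyle Behaviors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how meeting multiple lifestyle "pillars"
    (sleep, fruit and vegetable intake, sedentary time, physical activity,
    non-smoking) relates to body mass index and depressive symptoms in
    same-sex twin pairs. Provides survey coding rules for the five pillar
    indicators and the 0-5 pillar count; a synthetic twin-registry
    generator with ACE-structured liabilities; maximum-likelihood
    univariate ACE decomposition for continuous and ordinal twin traits
    with full-information handling of incomplete pairs; bivariate
    quasi-causal co-twin models that separate the within-pair association
    from between-family (genetic plus shared-environmental) confounding,
    with constraint sequences and Wald tests; regression trees over binary
    pillar indicators with surrogate splits, cost-complexity pruning by
    cross-validation, and summed-improvement variable importance; and
    descriptive between-individual and within-pair difference summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rpart
Config/testthat/edition: 3
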