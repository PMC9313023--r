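Package: idrbias
Title: Compositional Bias and Predictor Evaluation for Intrinsically Disordered Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of amino-acid compositional bias across classes of
    intrinsic protein disorder (fully disordered proteins, short, long and
    binding intrinsically disordered regions), per-residue evaluation of
    disorder predictors (AUC, AUPR, MCC, F1) overall and per disorder class,
    bootstrap-based significance comparison of predictors, and a class-routed
    meta-predictor that assigns each protein to the component predictor best
    suited to its disorder class. Includes readers and writers for CAID-style
    per-residue reference and prediction files and for amino-acid propensity
    scales, and a synthetic-data generator that emulates CAID-like datasets
    with controllable composition enrichments and per-class predictor
    discrimination so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
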