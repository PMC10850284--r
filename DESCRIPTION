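Package: sepsig
Title: Discovery and Evaluation of Sepsis and SIRS Transcriptomic Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and benchmarking blood-transcriptome
    biomarker panels that separate sepsis from non-infectious systemic
    inflammation (SIRS). Provides a seeded synthetic cohort generator with
    planted fold-change effects, percentile-shift and median-baseline
    normalization for one-colour microarray data, differential statistics
    (signed fold change, t/ANOVA/Mann-Whitney with Benjamini-Hochberg FDR,
    PCA), stepwise multilayer-perceptron feature selection with Monte-Carlo
    cross-validation, random-forest importance ranking with iterative
    elimination, and signed additive composite panel scoring with full ROC,
    cut-off and diagnostic-metric machinery (PPV/NPV targeting, likelihood
    ratios, Hanley-McNeil confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    randomForest,
    withr,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
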