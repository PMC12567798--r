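Package: toxscreen
Title: Protein Toxicity Prediction from Sequence Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building and evaluating sequence-based predictors of
    protein toxicity. Implements FASTA cleaning rules for toxin datasets,
    eight classical descriptor families (amino acid and dipeptide composition,
    Moreau-Broto, Moran and Geary autocorrelation, composition, transition and
    distribution descriptors, conjoint triad, quasi-sequence-order, pseudo and
    amphiphilic pseudo amino acid composition), AAindex profiles, PSI-BLAST
    PSSM parsing with global average pooling, discriminative minimotif mining,
    clustering-based negative sampling with elbow k selection, a four-stage
    feature-selection cascade (zero variance, Pearson correlation, graphical
    ensemble co-selection, recursive feature elimination with
    cross-validation), gradient-boosted classification with nested
    cross-validation, and a balanced evaluation suite including the Matthews
    correlation coefficient and the overall performance measure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    seqinr,
    xgboost,
    randomForest,
    e1071,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
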