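# toxscreen

Sequence-based prediction of protein toxicity.

Protein toxins — venom components, bacterial exotoxins, plant toxins —
are annotated for only a small fraction of known proteins, and assaying
toxicity experimentally is slow and expensive. `toxscreen` is an R toolkit
for building, auditing and applying machine-learning predictors that
classify a protein as toxic or non-toxic from its amino-acid sequence
alone. It is aimed at bioinformaticians screening sequencing-project or
designed proteins, and at methods developers who need a transparent,
fully-tested reference implementation of the classical
descriptor-plus-gradient-boosting pipeline.

## What the package implements

**Features.** Each cleaned sequence (length ≥ 35, standard residues only)
is described by 1920 classical descriptors in eight families — amino acid
composition (20), dipeptide composition (400), normalized Moreau–Broto,
Moran and Geary autocorrelation over eight physicochemical scales at lags
1–30 (3 × 240), composition/transition/distribution (147), conjoint triad
(343), quasi-sequence-order with sequence-order coupling numbers (160),
and pseudo / amphiphilic pseudo amino acid composition (50 + 80) — plus a
20-value evolutionary profile obtained by global average pooling of a
PSI-BLAST PSSM, `GAP_j = (1/L) Σ_i P_ij`, six physicochemical group counts
with sequence length, 50 one-hot discriminative minimotifs (substrings
present in toxins and absent from non-toxins), and optional AAindex
profile means.

**Class balance.** Non-toxins outnumber toxins by orders of magnitude, so
the negative pool is k-means-clustered in feature space, k is chosen where
the SSE curve `SSE = Σ_j Σ_{x∈C_j} ‖x − c_j‖²` stops dropping steeply
(automated second-difference elbow rule), and representatives are sampled
per cluster in proportion to cluster size — retaining rare sequence types
that uniform undersampling would miss.

**Feature selection.** A four-stage cascade with a full audit trail:
zero-variance removal → greedy Pearson filter (drop the later feature of
any pair with |r| ≥ 0.8) → graphical ensemble feature selection (bootstrap
gradient-boosted learners vote; features ranked by weighted degree in the
co-selection graph) → recursive feature elimination with cross-validation
(1-SE rule). A packaged 88-feature manifest reproduces a published
selected-feature space.

**Models and evaluation.** Two gradient-boosting variants, random forest
and an SVM behind one interface; stratified 20-fold (95/5)
cross-validation in which every label-using step — motif mining, GEFS,
RFECV — is refit inside each training fold (an instrumented recorder
proves it); sequential model-based hyperparameter tuning; and ten
performance measures from the confusion counts, including the Matthews
correlation coefficient, its rescaling nMCC = (1 + MCC)/2, and the
balanced summary

    OPM = (NPV + PPV) · (specificity + sensitivity) · (accuracy + nMCC) / 8.

## Worked example

```r
library(toxscreen)

# synthetic benchmark: cysteine-rich toxin-like positives vs background
b <- make_benchmark("tiny")

pipe <- fit_toxin_pipeline(b$train$pos, b$train$neg, seed = 1,
  gefs  = list(n_members = 5, member_top = 20, top_k = 20, nrounds = 10),
  rfecv = list(cv_folds = 3, nrounds = 10), nrounds = 30)
pipe
#> <tox_pipeline> gradient-boosting-A, 50 motifs mined, 1 features

newd <- generate_synthetic(synthetic_spec(n_pos = 3, n_neg = 3, seed = 99))
rbind(predict(pipe, newd$pos), predict(pipe, newd$neg))
#>         id probability label
#> 1 TOX00001      0.5917     1
#> 2 TOX00002      0.9574     1
#> 3 TOX00003      0.9574     1
#> 4 NEG00001      0.0398     0
#> 5 NEG00002      0.0398     0
#> 6 NEG00003      0.0398     0
```

On this tiny benchmark the cascade's parsimony rule keeps a single
feature — `C`, the cysteine fraction — and still separates the classes:
the planted signal is cysteine enrichment, and composition captures it.
Probabilities above the 0.5 threshold are labelled toxin (1).

Metric arithmetic from published confusion counts:

```r
metrics_from_counts(confusion_counts(TP = 225, TN = 457, FP = 17, FN = 54))
#> <metrics_report>
#>   NPV          0.894
#>   PPV          0.930
#>   specificity  0.964
#>   sensitivity  0.806
#>   accuracy     0.906
#>   MCC          0.797
#>   nMCC         0.898
#>   OPM          0.728
#>   F1           0.864
#>   AUC          NA
```

A command-line front end wraps each stage
(`exec/toxscreen simulate|clean|featurize|motifs|sample|select|train|predict|evaluate`);
every run echoes its configuration and hash next to its outputs.

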