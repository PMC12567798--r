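---
title: "Methods: sequence-based protein toxicity prediction with toxscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based protein toxicity prediction with toxscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the modelling approach

Protein toxins are a heterogeneous class — venom peptides, pore-forming
bacterial toxins, ribosome-inactivating plant proteins — but they share
recognisable sequence-level regularities: many are short, secreted,
disulfide-stabilised and hence cysteine-rich, and they carry recurrent
short motifs. `toxscreen` treats toxicity prediction as supervised binary
classification on a fixed-length numeric description of the sequence,
with gradient-boosted decision trees as the default learner. The pipeline
assumes only that a sequence is a string over the 20 standard residues of
length at least 35; no structure, annotation or homology search is
required (an evolutionary profile improves the description when a
PSI-BLAST database is available, but a deterministic substitution-matrix
fallback keeps the pipeline self-contained).

## Sequence cleaning

`clean_sequences()` removes sequences shorter than 35 residues and
sequences containing any of B, J, O, U, X, Z (ambiguity codes,
selenocysteine/pyrrolysine, unknowns). Rationale: very short peptides are
handled poorly by lag- and window-based descriptors (all lag parameters
default to 30, and a descriptor is only defined when the sequence is
longer than its lag), and non-standard residues have no values in the
physicochemical scales. Lowercase input is uppercased and terminal `*`
stop codons stripped before the rules apply; every rejection is logged
with its reason, and cleaning is idempotent. Duplicate ids are an error
rather than silently renamed; duplicate sequences under distinct ids are
kept, since deduplication is a dataset-design decision, not a validity
rule.

## Descriptor families

The classical families follow the conventions of the protr descriptor
library (naming included), so published feature lists remain readable:

* **aac / dpc** — relative frequencies of residues and overlapping
  dipeptides (20 + 400; each sums to 1).
* **Autocorrelation (mb / moran / geary)** — normalized Moreau–Broto,
  Moran and Geary statistics of physicochemical profiles, 8 AAindex
  scales × 30 lags each (720 total). Property scales are z-scored over
  the 20 residues with the population (n = 20) standard deviation before
  being mapped onto the sequence. On a zero-variance profile
  (e.g. a homopolymer) Moran and Geary are 0 by definition here rather
  than 0/0; these degenerate columns are removed by selection anyway.
* **ctd** — for seven three-class encodings (hydrophobicity, normalized
  van der Waals volume, polarity, polarizability, charge, secondary
  structure, solvent accessibility): class fractions, adjacent
  cross-class transition fractions (denominator L − 1; defined as 0 for
  L = 1), and the percent positions of the 1st/25%/50%/75%/100%
  occurrence of each class (0 when the class is absent). 147 values.
* **Conjoint triad** — frequencies of the 343 class-triads over the
  seven-group alphabet, normalized as (f − min f)/max f, the original
  convention for this family; the normalization choice is echoed in the
  configuration object for auditability.
* **qso / socn** — sequence-order coupling numbers
  τ_d = Σ_i d(R_i, R_{i+d})² for lags 1–30 under two inter-residue
  distance matrices, plus the quasi-sequence-order descriptors built from
  them (w = 0.1). The second matrix is the Grantham distance, computed in
  code from the published composition/polarity/volume values and
  constants and verified against well-known entries (Leu–Ile 5, Trp–Cys
  215, Arg–Leu 102). For the physicochemical slot that this descriptor
  family conventionally fills with the Schneider–Wrede matrix, the
  package computes its own side-chain distance — the root mean squared
  difference of the z-scored PAAC property trio (hydrophobicity,
  hydrophilicity, side-chain mass) — and names those features `scdist.*`.
  It plays the same role but differs numerically from the Schneider–Wrede
  values; the packaged feature-manifest resolver maps published
  `Schneider.*` names onto the `scdist.*` columns and records the
  mapping.
* **paac / apaac** — pseudo and amphiphilic pseudo amino acid composition
  (λ = 30, w = 0.05) over the same property trio.
* **PSSM pool** — global average pooling of the L × 20 PSI-BLAST
  log-odds matrix (the first 20-column block of the ASCII output; the
  percentage block is ignored) into `PSSM_A` … `PSSM_Y`, reordered
  alphabetically from PSI-BLAST's native column order. Three providers:
  live `psiblast` (E-value 0.001, 3 iterations), a directory of
  precomputed ASCII PSSMs, and a deterministic fallback that substitutes
  the BLOSUM62 row of each residue — useful when no database is at hand,
  and flagged by a provenance field so profile-free features are never
  mistaken for evolutionary ones.
* **Groups + length** — counts in six physicochemical groups
  (hydrophobic VILFMWYC, negative DE, positive RKH, conformational GP,
  polar NQS, other AT) plus the raw length. Length is deliberately left
  unnormalized; scaling is the model pipeline's concern.
* **Minimotifs** — literal substrings of length 3–6 present in ≥ 1
  positive and 0 negatives, ranked by positive coverage (ties: shorter,
  then lexicographic), top 50 kept, one-hot encoded. Degenerate
  physicochemical-class motifs and gapped patterns are out of scope: the
  downstream contract consumes only binary flags, and literal mining
  keeps the search exhaustive and exactly testable.
* **AAindex profile** — per-index mean over the sequence; the default
  table is the AAindex1 collection bundled with seqinr, restricted to
  indices with complete values. The family is off by default so that the
  default feature space has a fixed, documented width (1997 columns with
  PSSM, groups and 50 motifs).

At default configuration the eight classical families contribute exactly
20 + 400 + 720 + 147 + 343 + 160 + 50 + 80 = 1920 columns. In the
assembled matrix the three autocorrelation families carry `mb.`, `moran.`
and `geary.` prefixes — their per-family names coincide, and column names
must be unique.

## Balanced negative sampling

Toxin corpora are heavily imbalanced, so the negative pool is clustered
with k-means (best of 10 restarts, Lloyd's algorithm) on z-scored
features; constant columns are left unscaled rather than dividing by
zero. The number of clusters is scanned (k = 2…20 by default) and chosen
by an automated elbow rule: the k maximizing the discrete second
difference SSE(k−1) − 2·SSE(k) + SSE(k+1), ties to the smallest k.
Automating what is usually a visual judgement makes the choice
reproducible; the SSE curve is exported for manual inspection. Negatives
are then drawn per cluster with quotas proportional to cluster size
under largest-remainder rounding, with every non-empty cluster
guaranteed one representative when the total allows — the point of
cluster-based sampling is precisely that rare sequence types stay
represented. Quotas are capped at cluster sizes with deterministic
redistribution of any overflow.

## The selection cascade

1. **Zero variance** — drop columns with sd = 0.
2. **Pearson filter** — greedy scan in fixed column order dropping the
   later member of any pair with |r| ≥ 0.8. The threshold is applied to
   |r|: a feature and its negation carry the same information. Keeping
   the earlier column makes the stage deterministic and idempotent.
3. **GEFS** — 20 gradient-boosted members on bootstrap resamples, each
   nominating its top 50 features by gain; co-selection graph with edge
   weights = number of members selecting both endpoints; rank by
   weighted degree (ties: selection count, then name); keep the top 100.
   Member count and nomination size are stability/runtime compromises
   and fully configurable.
4. **RFECV** — drop the least-important feature one at a time (gain of a
   fit on the full training data; never-used features first), score every
   subset size by k-fold CV accuracy with a fold assignment fixed across
   sizes, and return the smallest subset within one standard error of the
   best score. The 1-SE rule yields a reproducible, parsimonious size
   instead of an argmax that flips between near-ties.

Every stage emits an audit record (features in, dropped with reason and
correlated partner, features out); the records chain exactly, which the
tests assert as in − dropped = out at every stage.

## Classifier, cross-validation and leakage control

Four algorithm families sit behind one interface: exact-greedy gradient
boosting (the default), a histogram/leaf-wise gradient-boosting variant
(`tree_method = "hist"`, `grow_policy = "lossguide"` — the design choices
that distinguish LightGBM-style learners), random forest, and a
radial-kernel SVM with probability outputs. All training is
single-threaded and seeded, so results are bit-reproducible. The decision
threshold is 0.5 with ≥ on the boundary; it is a stored model property so
screening applications can trade sensitivity for specificity explicitly.

Cross-validation is stratified 20-fold, i.e. 95/5 train/validation
splits, and metrics are reported both as means of per-fold metrics (the
convention of fold-averaged comparison tables, and the package's primary
report) and as metrics of pooled counts — the two differ in the third
decimal, so both are exposed. Everything that learns from labels — motif
mining, GEFS, RFECV, scaling, the model itself — must be refit inside
each training fold. This is enforced structurally (the pipeline object
is refit per fold in `nested_cv_pipeline()`) and audited dynamically: a
label-access recorder collects the ids whose labels each stage touched,
and the tests assert per fold that the recorded set is contained in the
training ids and disjoint from the validation ids.

Hyperparameter tuning is sequential model-based optimisation of the mean
CV MCC: a maximin Latin-hypercube initial design, then a random-forest
surrogate whose across-tree spread provides the exploration term of an
upper-confidence-bound acquisition over a random candidate pool. The
default space covers tree count 100–2000, depth 3–10, learning rate
10⁻³–0.3 (log scale), row/column subsampling 0.5–1 and minimum child
weight 1–10, with a budget of 50 evaluations; the full trace is returned.

## Evaluation measures

All ten measures derive from TP/TN/FP/FN (counts may be fractional,
because fold-averaged tables report mean counts): NPV, PPV, specificity,
sensitivity, accuracy, MCC, nMCC = (1 + MCC)/2, OPM = (NPV + PPV) ×
(specificity + sensitivity) × (accuracy + nMCC)/8, F1, and a rank-based
AUC (Mann–Whitney with half-credit for ties) when scores are available.
Ratios with zero denominators are defined as 0 and flagged, and MCC with
a zero denominator is 0, so OPM stays defined for degenerate classifiers.
Display rounding is half-away-from-zero at 3 decimals, matching common
table conventions (R's default round-half-even would differ on exact
5s).

## The synthetic benchmark

`generate_synthetic()` emulates the shape of the real problem: positives
are short (lognormal lengths, median ≈ 90, truncated to [35, 400]),
cysteine-enriched (default ×3 before renormalization), carry five
cysteine-rich 5-mer minimotifs each planted independently with
probability 0.6 at non-overlapping positions, and have a mild CC
dipeptide bias; negatives are drawn from proteome-like background
frequencies and are rejection-sampled to be motif-free. The signal is
deliberately multi-channel — composition, motifs and dipeptides — so
recovery tests can distinguish which descriptor families carry
information. Presets: `tiny` (20/20), `default` (400/400 train, 100/100
test) and `imbalanced` (200/6000).

What the generator does **not** emulate: homology structure between
sequences (so cross-validation folds are truly independent, unlike real
protein families), realistic evolutionary profiles (synthetic runs use
the BLOSUM62 fallback), domain architecture, and label noise. Passing
tests on this benchmark therefore demonstrates the correctness and
discriminative machinery of the pipeline, not the accuracy attainable on
real proteome-scale data; the desk-scale end-to-end check (held-out
accuracy ≥ 0.85, MCC ≥ 0.7 on the `default` preset) stands in for a
corpus-scale experiment that is out of scope here.

## Problem sizes used by the test suite

The suite is sized for a single CPU: descriptor oracles run exhaustively
over all two-letter sequences up to length 10 plus 100 random sequences
of length 35–200; selection-recovery uses 20 replicates of 300 × 100
matrices with 5 informative columns; the end-to-end run uses the
`default` preset (800 training, 200 test sequences, 1997 features); the
leakage audit runs 5 nested folds on the `tiny` preset.

## Known limitations

* The side-chain physicochemical distance matrix is a package-defined
  stand-in for the Schneider–Wrede matrix (see above); coupling numbers
  under it are internally consistent but not numerically comparable to
  implementations shipping the original matrix.
* The bundled AAindex1 table does not contain every accession that has
  appeared in published selected-feature lists (AAindex2/3 matrix
  accessions in particular); the manifest resolver reports such names as
  unresolved unless a user-supplied table provides them.
* Minimotif mining is literal and exhaustive; it does not generalise to
  degenerate alphabets.
* k-means uses Lloyd's algorithm with restarts; on adversarial data the
  elbow rule can select a k a human would not, which is why the SSE
  curve is always exported.
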