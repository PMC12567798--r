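# End-to-end pipeline: motif mining, featurization, selection cascade and
# classifier training behind one object, with per-fold refitting for nested
# cross-validation.

#' Stack positive and negative feature matrices
#'
#' @param fm_pos,fm_neg Feature matrices with identical columns.
#' @return List with `fm` (row-bound matrix) and `labels` (1 for the
#'   positive block, 0 for the negative block).
#' @export
stack_feature_matrices <- function(fm_pos, fm_neg) {
  stopifnot(identical(colnames(fm_pos), colnames(fm_neg)))
  fm <- rbind(fm_pos, fm_neg)
  labels <- c(rep(1L, nrow(fm_pos)), rep(0L, nrow(fm_neg)))
  list(fm = fm, labels = stats::setNames(labels, rownames(fm)))
}

#' Fit the full toxin-prediction pipeline
#'
#' Mines discriminative minimotifs from the training sequences, featurizes
#' both classes, optionally runs the four-stage selection cascade, and
#' trains the classifier on the surviving features. Every label-using step
#' (motif mining, GEFS, RFECV, model fitting) sees only the sequences
#' passed here, and reports to the optional recorder, so the pipeline can
#' be refit inside cross-validation folds without information leakage.
#'
#' @param pos,neg Cleaned [tox_dataset()]s (toxins / non-toxins).
#' @param config A [descriptor_config()].
#' @param pssm_provider PSSM provider (default: BLOSUM62 fallback).
#' @param select Run the selection cascade (default TRUE).
#' @param algorithm Classifier algorithm id.
#' @param nrounds Boosting rounds for the final model.
#' @param motif_top_k Motifs mined (default 50).
#' @param gefs,rfecv Argument lists forwarded to the cascade stages.
#' @param seed Random seed.
#' @param recorder Optional [label_access_recorder()].
#' @return A `tox_pipeline` with the motif set, feature list, selection
#'   report and fitted model; use `predict()` on new datasets.
#' @export
fit_toxin_pipeline <- function(pos, neg, config = descriptor_config(),
                               pssm_provider = pssm_provider_fallback(),
                               select = TRUE,
                               algorithm = "gradient-boosting-A",
                               nrounds = 100L, motif_top_k = 50L,
                               gefs = list(), rfecv = list(),
                               seed = 1L, recorder = NULL) {
  motifs <- discover_motifs(pos, neg, top_k = motif_top_k,
                            recorder = recorder)
  fm_pos <- featurize(pos, config, pssm_provider, motifs)
  fm_neg <- featurize(neg, config, pssm_provider, motifs)
  st <- stack_feature_matrices(fm_pos, fm_neg)
  report <- NULL; graph <- NULL
  if (isTRUE(select)) {
    casc <- run_selection_cascade(st$fm, st$labels, gefs = gefs,
                                  rfecv = rfecv, seed = seed,
                                  recorder = recorder)
    features <- casc$features
    report <- casc$report
    graph <- casc$graph
  } else {
    features <- colnames(st$fm)
  }
  model <- train_classifier(st$fm[, features, drop = FALSE], st$labels,
                            algorithm = algorithm, nrounds = nrounds,
                            seed = seed, recorder = recorder)
  structure(list(motifs = motifs, config = config,
                 pssm_provider = pssm_provider, features = features,
                 selection_report = report, graph = graph, model = model,
                 seed = seed),
            class = "tox_pipeline")
}

#' @export
print.tox_pipeline <- function(x, ...) {
  cat(sprintf("<tox_pipeline> %s, %d motifs mined, %d features\n",
              x$model$algorithm, nrow(x$motifs), length(x$features)))
  invisible(x)
}

#' Predict on new sequences with a fitted pipeline
#'
#' Featurizes the dataset with the stored configuration and motif set and
#' applies the trained classifier.
#'
#' @param object A `tox_pipeline`.
#' @param ds A cleaned [tox_dataset()].
#' @param ... Unused.
#' @return Data frame with `id`, `probability`, `label`.
#' @export
predict.tox_pipeline <- function(object, ds, ...) {
  fm <- featurize(ds, object$config, object$pssm_provider, object$motifs)
  predict(object$model, fm)
}

#' Nested cross-validation over sequences
#'
#' Stratified n-fold CV where the entire pipeline -- motif mining,
#' selection cascade, classifier -- is refit from scratch on each training
#' fold and applied to the held-out fold. With a recorder, each fold's
#' label accesses are audited against its training ids.
#'
#' @param pos,neg Cleaned datasets.
#' @param n_folds Number of folds (default 20, i.e. 95/5 splits).
#' @param seed Random seed.
#' @param ... Passed to [fit_toxin_pipeline()].
#' @param audit Record and audit label accesses per fold (default TRUE).
#' @return List with `metrics_mean`, `metrics_pooled`, `fold_counts`,
#'   `mean_counts` and `leakage` (per-fold audit records).
#' @export
nested_cv_pipeline <- function(pos, neg, n_folds = 20L, seed = 1L,
                               audit = TRUE, ...) {
  ids <- c(pos$id, neg$id)
  labels <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  fold <- make_cv_folds(labels, n_folds, seed)
  fold_counts <- list(); fold_metrics <- list(); leakage <- list()
  pooled_truth <- integer(0); pooled_pred <- integer(0)
  pooled_prob <- numeric(0)
  for (f in seq_len(n_folds)) {
    tr_pos <- subset_dataset(pos, fold[seq_along(pos$id)] != f)
    tr_neg <- subset_dataset(neg, fold[length(pos$id) + seq_along(neg$id)] != f)
    va_pos <- subset_dataset(pos, fold[seq_along(pos$id)] == f)
    va_neg <- subset_dataset(neg, fold[length(pos$id) + seq_along(neg$id)] == f)
    rec <- if (audit) label_access_recorder() else NULL
    pipe <- fit_toxin_pipeline(tr_pos, tr_neg, seed = seed + f,
                               recorder = rec, ...)
    truth <- c(rep(1L, length(va_pos)), rep(0L, length(va_neg)))
    va_ids <- c(va_pos$id, va_neg$id)
    preds <- rbind(
      if (length(va_pos) > 0L) predict(pipe, va_pos),
      if (length(va_neg) > 0L) predict(pipe, va_neg))
    cc <- counts_from_predictions(truth, preds$label)
    fold_counts[[f]] <- cc
    fold_metrics[[f]] <- metrics_from_counts(cc, preds$probability, truth)
    pooled_truth <- c(pooled_truth, truth)
    pooled_pred <- c(pooled_pred, preds$label)
    pooled_prob <- c(pooled_prob, preds$probability)
    if (audit) {
      touched <- recorded_ids(rec)
      train_ids <- c(tr_pos$id, tr_neg$id)
      leakage[[f]] <- list(fold = f, touched = touched,
                           train_ids = train_ids,
                           validation_ids = va_ids,
                           ok = all(touched %in% train_ids))
    }
  }
  mean_counts <- confusion_counts(
    TP = mean(vapply(fold_counts, `[[`, numeric(1), "TP")),
    TN = mean(vapply(fold_counts, `[[`, numeric(1), "TN")),
    FP = mean(vapply(fold_counts, `[[`, numeric(1), "FP")),
    FN = mean(vapply(fold_counts, `[[`, numeric(1), "FN")))
  metric_names <- c("NPV", "PPV", "specificity", "sensitivity", "accuracy",
                    "MCC", "nMCC", "OPM", "F1", "AUC")
  metrics_mean <- lapply(metric_names, function(m)
    mean(vapply(fold_metrics, function(x) x[[m]], numeric(1))))
  names(metrics_mean) <- metric_names
  class(metrics_mean) <- "metrics_report"
  list(metrics_mean = metrics_mean,
       metrics_pooled = metrics_from_counts(
         counts_from_predictions(pooled_truth, pooled_pred),
         scores = pooled_prob, labels = pooled_truth),
       fold_counts = fold_counts, mean_counts = mean_counts,
       leakage = if (audit) leakage else NULL)
}
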