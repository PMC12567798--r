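# Binary toxin classifier: four algorithm families behind one interface,
# stratified 20-fold cross-validation with per-fold refitting of every
# label-dependent step, sequential model-based hyperparameter tuning, and a
# label-access recorder used to audit the no-leakage contract.

ALGORITHMS <- c("gradient-boosting-A", "gradient-boosting-B",
                "random-forest", "support-vector")

#' Label-access recorder
#'
#' Instrumentation for the no-leakage contract: stages that learn from
#' labels (motif mining, GEFS, RFECV, model fitting) record the ids of the
#' rows whose labels they touched. Tests assert that inside every
#' cross-validation fold the recorded ids are a subset of that fold's
#' training ids.
#'
#' @return A recorder (environment with an `ids` character vector).
#' @export
label_access_recorder <- function() {
  rec <- new.env(parent = emptyenv())
  rec$ids <- character(0)
  class(rec) <- "label_access_recorder"
  rec
}

#' @rdname label_access_recorder
#' @param recorder A recorder.
#' @param ids Ids whose labels were accessed.
#' @export
record_label_access <- function(recorder, ids) {
  if (is.null(ids)) return(invisible(NULL))
  recorder$ids <- union(recorder$ids, ids)
  invisible(NULL)
}

#' @rdname label_access_recorder
#' @export
recorded_ids <- function(recorder) recorder$ids

xgb_params_for <- function(algorithm, params, seed) {
  base <- list(objective = "binary:logistic", nthread = 1, seed = seed)
  if (algorithm == "gradient-boosting-B") {
    # histogram binning + leaf-wise growth (LightGBM-style variant)
    base <- c(base, list(tree_method = "hist", grow_policy = "lossguide",
                         max_leaves = 31))
  } else {
    base <- c(base, list(tree_method = "exact"))
  }
  utils::modifyList(base, params)
}

#' Train a toxin classifier
#'
#' Fits one of the four supported algorithm families: two gradient-boosting
#' variants (exact greedy trees, the default and published winner; and a
#' histogram/leaf-wise variant), random forest, or a radial-kernel support
#' vector machine. Deterministic for a fixed seed in single-threaded mode.
#'
#' @param fm Feature matrix (rows = samples, named columns).
#' @param labels 0/1 vector (1 = toxin); both classes must be present.
#' @param algorithm One of `"gradient-boosting-A"`, `"gradient-boosting-B"`,
#'   `"random-forest"`, `"support-vector"`.
#' @param params Named list of algorithm parameters (defaults otherwise).
#' @param nrounds Boosting rounds for the gradient-boosting families.
#' @param seed Random seed.
#' @param threshold Decision threshold on the toxin probability
#'   (label = probability >= threshold; default 0.5).
#' @param recorder Optional [label_access_recorder()].
#' @return A `tox_model` (algorithm id, fitted object, ordered feature
#'   names, threshold, seed).
#' @export
train_classifier <- function(fm, labels,
                             algorithm = "gradient-boosting-A",
                             params = list(), nrounds = 100L, seed = 1L,
                             threshold = 0.5, recorder = NULL) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  stopifnot(is.matrix(fm))
  labels <- as.integer(labels)
  if (nrow(fm) != length(labels))
    stop("feature/label length mismatch: ", nrow(fm), " vs ", length(labels))
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  if (!is.null(recorder)) record_label_access(recorder, rownames(fm))
  set.seed(seed)
  fit <- switch(algorithm,
    "gradient-boosting-A" = ,
    "gradient-boosting-B" = {
      d <- xgboost::xgb.DMatrix(fm, label = labels, nthread = 1)
      xgboost::xgb.train(params = xgb_params_for(algorithm, params, seed),
                         data = d, nrounds = nrounds, verbose = 0)
    },
    "random-forest" = {
      args <- utils::modifyList(list(x = fm, y = factor(labels,
                                                        levels = c(0, 1)),
                                     ntree = 500), params)
      do.call(randomForest::randomForest, args)
    },
    "support-vector" = {
      args <- utils::modifyList(list(x = fm, y = factor(labels,
                                                        levels = c(0, 1)),
                                     kernel = "radial", probability = TRUE,
                                     scale = TRUE), params)
      do.call(e1071::svm, args)
    })
  structure(list(algorithm = algorithm, fit = fit,
                 features = colnames(fm), threshold = threshold,
                 seed = seed, params = params, nrounds = nrounds),
            class = "tox_model")
}

#' @export
print.tox_model <- function(x, ...) {
  cat(sprintf("<tox_model> %s, %d features, threshold %.2f\n",
              x$algorithm, length(x$features), x$threshold))
  invisible(x)
}

#' Predict toxin probabilities and labels
#'
#' Columns bind by name, not position: the input may hold extra columns in
#' any order, but every stored feature must be present (missing columns are
#' an error listing their names). A probability equal to the threshold is
#' labelled toxin.
#'
#' @param object A `tox_model`.
#' @param newdata Feature matrix whose columns include the model features.
#' @param ... Unused.
#' @return Data frame with `id`, `probability`, `label` (0/1).
#' @export
predict.tox_model <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing) > 0L)
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  x <- newdata[, object$features, drop = FALSE]
  prob <- switch(object$algorithm,
    "gradient-boosting-A" = ,
    "gradient-boosting-B" = as.numeric(
      predict(object$fit, xgboost::xgb.DMatrix(x, nthread = 1))),
    "random-forest" = as.numeric(predict(object$fit, x,
                                         type = "prob")[, "1"]),
    "support-vector" = {
      p <- predict(object$fit, x, probability = TRUE)
      as.numeric(attr(p, "probabilities")[, "1"])
    })
  ids <- rownames(newdata)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(newdata)))
  data.frame(id = ids, probability = prob,
             label = as.integer(prob >= object$threshold),
             stringsAsFactors = FALSE)
}

#' Cross-validation scheme
#'
#' Stratified n-fold partition; each fold's validation split is 1/n of the
#' data (5% at the default 20 folds, i.e. a 95/5 train/validation split).
#'
#' @param n_folds Number of folds (default 20).
#' @param seed Random seed.
#' @return A `cv_scheme` list.
#' @export
cv_scheme <- function(n_folds = 20L, seed = 1L) {
  stopifnot(n_folds >= 2L)
  structure(list(n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Cross-validate a classifier
#'
#' Stratified n-fold cross-validation. Any label-dependent preprocessing
#' (motif mining, feature selection, scaling) must be refit inside each
#' training fold: pass it as `preprocess`, a function
#' `(fm_train, labels_train, recorder) -> list(fm = transformed training
#' matrix, transform = function(fm_new) ...)`. Metrics are reported both as
#' means of per-fold metrics (matching fold-averaged comparison tables) and
#' as metrics of pooled counts.
#'
#' @param fm Feature matrix.
#' @param labels 0/1 vector.
#' @param algorithm Algorithm id, see [train_classifier()].
#' @param scheme A [cv_scheme()].
#' @param params,nrounds Passed to [train_classifier()].
#' @param preprocess Optional per-fold preprocessing closure (see above).
#' @param recorder Optional [label_access_recorder()]; reset and checked
#'   per fold, with any violation reported in the result.
#' @return List with `fold_counts` (per-fold confusion counts),
#'   `mean_counts`, `metrics_mean`, `metrics_pooled`, `fold_assignment`,
#'   and `leakage` (per-fold audit, when a recorder is supplied).
#' @export
cross_validate <- function(fm, labels, algorithm = "gradient-boosting-A",
                           scheme = cv_scheme(), params = list(),
                           nrounds = 100L, preprocess = NULL,
                           recorder = NULL) {
  stopifnot(inherits(scheme, "cv_scheme"))
  labels <- as.integer(labels)
  fold <- make_cv_folds(labels, scheme$n_folds, scheme$seed)
  ids <- rownames(fm)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(fm)))
  fold_counts <- list()
  fold_metrics <- list()
  leakage <- list()
  pooled_truth <- integer(0); pooled_pred <- integer(0)
  pooled_prob <- numeric(0)
  for (f in seq_len(scheme$n_folds)) {
    tr <- fold != f
    if (length(unique(labels[!tr])) < 1L || sum(!tr) == 0L)
      stop("empty validation fold; reduce n_folds")
    fold_rec <- if (is.null(recorder)) NULL else label_access_recorder()
    x_tr <- fm[tr, , drop = FALSE]; y_tr <- labels[tr]
    x_va <- fm[!tr, , drop = FALSE]
    if (!is.null(preprocess)) {
      pp <- preprocess(x_tr, y_tr, fold_rec)
      x_tr <- pp$fm
      x_va <- pp$transform(x_va)
    }
    model <- train_classifier(x_tr, y_tr, algorithm = algorithm,
                              params = params, nrounds = nrounds,
                              seed = scheme$seed + f, recorder = fold_rec)
    pred <- predict(model, x_va)
    cc <- counts_from_predictions(labels[!tr], pred$label)
    fold_counts[[f]] <- cc
    fold_metrics[[f]] <- metrics_from_counts(cc, scores = pred$probability,
                                             labels = labels[!tr])
    pooled_truth <- c(pooled_truth, labels[!tr])
    pooled_pred <- c(pooled_pred, pred$label)
    pooled_prob <- c(pooled_prob, pred$probability)
    if (!is.null(fold_rec)) {
      touched <- recorded_ids(fold_rec)
      leakage[[f]] <- list(fold = f,
                           touched = touched,
                           train_ids = ids[tr],
                           ok = all(touched %in% ids[tr]))
      record_label_access(recorder, touched)
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
  metrics_pooled <- metrics_from_counts(
    counts_from_predictions(pooled_truth, pooled_pred),
    scores = pooled_prob, labels = pooled_truth)
  list(fold_counts = fold_counts, mean_counts = mean_counts,
       metrics_mean = metrics_mean, metrics_pooled = metrics_pooled,
       fold_assignment = stats::setNames(fold, ids),
       leakage = if (length(leakage)) leakage else NULL)
}

#' Sequential model-based hyperparameter tuning
#'
#' Bayesian-style optimisation of cross-validated MCC over a bounded
#' numeric/integer search space: a Latin-hypercube initial design, then a
#' random-forest surrogate proposing the candidate with the best upper
#' confidence bound (predicted mean + kappa * across-tree spread) among a
#' random candidate pool. Deterministic for a fixed seed; the full
#' evaluation trace is returned.
#'
#' @param fm,labels Training data.
#' @param algorithm Algorithm id.
#' @param search_space Named list; each element
#'   `list(lower =, upper =, integer = FALSE, log = FALSE)`.
#' @param budget Total number of objective evaluations (default 20).
#' @param n_init Initial design size (default `max(4, budget %/% 4)`).
#' @param cv_folds Folds for the inner CV objective (default 3).
#' @param seed Random seed.
#' @param nrounds Boosting rounds (unless tuned via the space).
#' @param kappa Exploration weight of the acquisition rule.
#' @return List with `best_params`, `best_score` (mean CV MCC) and `trace`
#'   (one row per evaluation).
#' @export
tune_hyperparameters <- function(fm, labels, algorithm = "gradient-boosting-A",
                                 search_space = default_search_space(),
                                 budget = 20L, n_init = NULL, cv_folds = 3L,
                                 seed = 1L, nrounds = 50L, kappa = 1.0) {
  if (length(search_space) == 0L) stop("empty search space")
  if (is.null(n_init)) n_init <- max(4L, budget %/% 4L)
  if (budget < n_init)
    stop("budget must cover at least the initial design (", n_init, ")")
  dims <- names(search_space)
  decode <- function(u) {  # unit-cube row -> parameter list
    p <- list()
    for (i in seq_along(dims)) {
      s <- search_space[[i]]
      lo <- s$lower; hi <- s$upper
      v <- if (isTRUE(s$log)) exp(log(lo) + u[i] * (log(hi) - log(lo)))
           else lo + u[i] * (hi - lo)
      if (isTRUE(s$integer)) v <- as.integer(round(v))
      p[[dims[i]]] <- v
    }
    p
  }
  objective <- function(p) {
    nr <- nrounds
    if ("nrounds" %in% names(p)) { nr <- p$nrounds; p$nrounds <- NULL }
    res <- cross_validate(fm, labels, algorithm = algorithm,
                          scheme = cv_scheme(n_folds = cv_folds,
                                             seed = seed),
                          params = p, nrounds = nr)
    res$metrics_mean$MCC
  }
  set.seed(seed)
  U <- lhs::maximinLHS(n_init, length(dims))
  trace_u <- U
  scores <- apply(U, 1, function(u) objective(decode(u)))
  while (nrow(trace_u) < budget) {
    set.seed(seed + nrow(trace_u))
    cand <- matrix(stats::runif(500 * length(dims)), ncol = length(dims))
    rf <- randomForest::randomForest(x = trace_u, y = scores, ntree = 200)
    pred_all <- predict(rf, cand, predict.all = TRUE)
    mu <- pred_all$aggregate
    sdv <- apply(pred_all$individual, 1, stats::sd)
    u_next <- cand[which.max(mu + kappa * sdv), , drop = TRUE]
    scores <- c(scores, objective(decode(u_next)))
    trace_u <- rbind(trace_u, u_next)
  }
  param_rows <- do.call(rbind, lapply(seq_len(nrow(trace_u)), function(i)
    as.data.frame(decode(trace_u[i, ]))))
  trace <- cbind(param_rows, score = scores)
  best <- which.max(scores)
  list(best_params = decode(trace_u[best, ]), best_score = scores[best],
       trace = trace)
}

#' Default tuning space for the gradient-boosting families
#'
#' @return Named list of bounded dimensions (tree count, depth, learning
#'   rate on a log scale, row/column subsampling, minimum child weight).
#' @export
default_search_space <- function() {
  list(nrounds = list(lower = 100, upper = 2000, integer = TRUE),
       max_depth = list(lower = 3, upper = 10, integer = TRUE),
       eta = list(lower = 1e-3, upper = 0.3, log = TRUE),
       subsample = list(lower = 0.5, upper = 1),
       colsample_bytree = list(lower = 0.5, upper = 1),
       min_child_weight = list(lower = 1, upper = 10))
}

#' Save / load a trained model
#'
#' Portable archive: a directory holding `meta.json` (algorithm, feature
#' list, threshold, seed, parameters) plus the fitted object (native
#' xgboost serialization for the boosting families, RDS for the others).
#'
#' @param model A `tox_model`.
#' @param path Directory to create.
#' @return Invisibly `path` (save) or the `tox_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "tox_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(algorithm = model$algorithm, features = model$features,
               threshold = model$threshold, seed = model$seed,
               params = model$params, nrounds = model$nrounds)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (model$algorithm %in% c("gradient-boosting-A", "gradient-boosting-B")) {
    xgboost::xgb.save(model$fit, file.path(path, "booster.ubj"))
  } else {
    saveRDS(model$fit, file.path(path, "fit.rds"))
  }
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  fit <- if (meta$algorithm %in% c("gradient-boosting-A",
                                   "gradient-boosting-B")) {
    xgboost::xgb.load(file.path(path, "booster.ubj"))
  } else {
    readRDS(file.path(path, "fit.rds"))
  }
  structure(list(algorithm = meta$algorithm, fit = fit,
                 features = meta$features, threshold = meta$threshold,
                 seed = meta$seed,
                 params = as.list(meta$params), nrounds = meta$nrounds),
            class = "tox_model")
}
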