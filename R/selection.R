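# Four-stage feature-selection cascade: zero-variance removal, Pearson
# correlation filter, graphical ensemble co-selection (GEFS), and recursive
# feature elimination with cross-validation (RFECV). Every stage emits an
# audit record; label-using stages accept a leakage recorder.

new_stage <- function(stage, features_in, features_out, dropped) {
  list(stage = stage,
       n_in = length(features_in),
       n_out = length(features_out),
       features_out = features_out,
       dropped = dropped)
}

#' Selection report accessors
#'
#' A `selection_report` is a list of per-stage records (`stage`, `n_in`,
#' `n_out`, `features_out`, `dropped`); at every stage
#' `n_in - nrow(dropped) == n_out`, and the output of one stage is the
#' input of the next.
#'
#' @param report A `selection_report`.
#' @param path Output path for the JSON export.
#' @return `write_selection_report` invisibly returns `path`.
#' @export
write_selection_report <- function(report, path) {
  jsonlite::write_json(lapply(unclass(report), function(s) {
    list(stage = s$stage, n_in = s$n_in, n_out = s$n_out,
         features_out = s$features_out, dropped = s$dropped)
  }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Drop zero-variance features
#'
#' Removes every column with standard deviation 0 (all samples identical);
#' errors if nothing would remain.
#'
#' @param fm Numeric feature matrix.
#' @return List with `fm` (filtered matrix) and `stage` (audit record).
#' @export
drop_zero_variance <- function(fm) {
  stopifnot(is.matrix(fm), ncol(fm) > 0L)
  sds <- apply(fm, 2, stats::sd)
  keep <- sds > 0 & !is.na(sds)
  if (!any(keep)) stop("all features have zero variance")
  gone <- colnames(fm)[!keep]
  dropped <- data.frame(feature = gone,
                        reason = rep("zero variance", length(gone)),
                        partner = rep(NA_character_, length(gone)),
                        value = rep(0, length(gone)),
                        stringsAsFactors = FALSE)
  stage <- new_stage("zero_variance", colnames(fm), colnames(fm)[keep],
                     dropped)
  list(fm = fm[, keep, drop = FALSE], stage = stage)
}

#' Pearson correlation filter
#'
#' Greedy scan in fixed column order: a column is dropped when its absolute
#' Pearson correlation with any earlier kept column reaches the threshold,
#' so afterwards no surviving pair has `|r| >= threshold`. Idempotent and
#' deterministic.
#'
#' @param fm Numeric feature matrix with no zero-variance columns.
#' @param threshold Absolute-correlation cutoff (default 0.8).
#' @return List with `fm` (filtered matrix) and `stage` (audit record with
#'   the correlated partner and `|r|` for every dropped feature).
#' @export
correlation_filter <- function(fm, threshold = 0.8) {
  stopifnot(is.matrix(fm), ncol(fm) > 0L)
  p <- ncol(fm)
  C <- abs(stats::cor(fm))
  keep <- logical(p)
  partner <- rep(NA_character_, p)
  rval <- rep(NA_real_, p)
  for (j in seq_len(p)) {
    prev <- which(keep[seq_len(j - 1L)])
    if (length(prev) == 0L) { keep[j] <- TRUE; next }
    hits <- prev[C[j, prev] >= threshold]
    if (length(hits) == 0L) {
      keep[j] <- TRUE
    } else {
      partner[j] <- colnames(fm)[hits[1L]]
      rval[j] <- C[j, hits[1L]]
    }
  }
  gone <- colnames(fm)[!keep]
  dropped <- data.frame(feature = gone,
                        reason = rep(sprintf("|r|>=%g with earlier feature",
                                             threshold), length(gone)),
                        partner = partner[!keep], value = rval[!keep],
                        stringsAsFactors = FALSE)
  stage <- new_stage("correlation_filter", colnames(fm),
                     colnames(fm)[keep], dropped)
  list(fm = fm[, keep, drop = FALSE], stage = stage)
}

# one gradient-boosted member fit; returns its top features by gain
gbt_member_top <- function(x, y, member_top, nrounds, params, seed) {
  d <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = c(list(objective = "binary:logistic", nthread = 1,
                    seed = seed), params),
    data = d, nrounds = nrounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = booster)
  utils::head(imp$Feature, member_top)
}

#' Graphical ensemble feature selection (GEFS)
#'
#' Trains an ensemble of gradient-boosted learners on bootstrap resamples;
#' each member nominates its top features by gain importance. A co-selection
#' graph is built with features as vertices and edge weights equal to the
#' number of members selecting both endpoints; features are ranked by
#' weighted degree (ties by total selection count, then name) and the top
#' `top_k` returned.
#'
#' @param fm Labeled feature matrix (after the correlation filter).
#' @param labels 0/1 vector (1 = toxin).
#' @param n_members Ensemble size (default 20).
#' @param member_top Features nominated per member (default 50).
#' @param top_k Features returned (default 100; all, with a warning, if
#'   fewer distinct features were ever selected).
#' @param seed Random seed.
#' @param nrounds,params Boosting rounds and extra parameters per member.
#' @param recorder Optional [label_access_recorder()] for leakage audits.
#' @return List with `features` (ordered top-k), `graph` (symmetric
#'   co-selection count matrix), `degree` (weighted degrees) and `stage`
#'   (audit record).
#' @export
gefs_top_features <- function(fm, labels, n_members = 20L, member_top = 50L,
                              top_k = 100L, seed = 1L, nrounds = 30L,
                              params = list(max_depth = 4), recorder = NULL) {
  stopifnot(is.matrix(fm), nrow(fm) == length(labels))
  if (!is.null(recorder)) record_label_access(recorder, rownames(fm))
  n <- nrow(fm)
  set.seed(seed)
  member_seeds <- sample.int(1e6, n_members)
  picks <- vector("list", n_members)
  for (m in seq_len(n_members)) {
    set.seed(member_seeds[m])
    idx <- sample.int(n, n, replace = TRUE)
    picks[[m]] <- gbt_member_top(fm[idx, , drop = FALSE], labels[idx],
                                 member_top, nrounds, params,
                                 seed = member_seeds[m])
  }
  selected <- sort(unique(unlist(picks)))
  M <- vapply(picks, function(p) selected %in% p, logical(length(selected)))
  M <- matrix(as.numeric(M), nrow = length(selected),
              dimnames = list(selected, NULL))
  graph <- M %*% t(M)  # co-selection counts; diagonal = selection counts
  wdeg <- rowSums(graph) - diag(graph)
  ord <- order(-wdeg, -diag(graph), selected)
  ranked <- selected[ord]
  if (length(ranked) < top_k)
    warning(sprintf("only %d distinct features were ever selected (< %d)",
                    length(ranked), top_k))
  features <- utils::head(ranked, top_k)
  gone <- setdiff(colnames(fm), features)
  dropped <- data.frame(feature = gone,
                        reason = rep("not in GEFS top-k by weighted degree",
                                     length(gone)),
                        partner = rep(NA_character_, length(gone)),
                        value = rep(NA_real_, length(gone)),
                        stringsAsFactors = FALSE)
  list(features = features, graph = graph,
       degree = stats::setNames(wdeg[ord], ranked),
       stage = new_stage("gefs", colnames(fm), features, dropped))
}

#' Export a co-selection graph as an edge list
#'
#' @param graph Symmetric co-selection count matrix from
#'   [gefs_top_features()].
#' @param path Output TSV path (`from`, `to`, `weight`; upper triangle,
#'   nonzero edges only).
#' @return Invisibly `path`.
#' @export
write_coselection_graph <- function(graph, path) {
  idx <- which(upper.tri(graph) & graph > 0, arr.ind = TRUE)
  df <- data.frame(from = rownames(graph)[idx[, 1]],
                   to = colnames(graph)[idx[, 2]],
                   weight = graph[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# stratified fold assignment, deterministic under seed
make_cv_folds <- function(labels, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

# mean CV accuracy (+ SE over folds) of a gradient-boosted fit on a subset
cv_score_subset <- function(fm, labels, fold, nrounds, params) {
  accs <- vapply(sort(unique(fold)), function(f) {
    tr <- fold != f
    d <- xgboost::xgb.DMatrix(fm[tr, , drop = FALSE],
                              label = labels[tr], nthread = 1)
    booster <- xgboost::xgb.train(
      params = c(list(objective = "binary:logistic", nthread = 1, seed = 7L),
                 params),
      data = d, nrounds = nrounds, verbose = 0)
    pred <- as.integer(
      predict(booster, xgboost::xgb.DMatrix(fm[!tr, , drop = FALSE],
                                            nthread = 1)) >= 0.5)
    mean(pred == labels[!tr])
  }, numeric(1))
  c(mean = mean(accs), se = stats::sd(accs) / sqrt(length(accs)))
}

#' Recursive feature elimination with cross-validation (RFECV)
#'
#' Starting from all columns, repeatedly scores the current subset by
#' k-fold cross-validated accuracy, then removes the least-important
#' feature (gain importance of a fit on the full training data; features
#' never used by the model are removed first). The returned subset is the
#' smallest whose mean CV score is within one standard error of the best
#' score (the 1-SE parsimony rule). Step size is 1.
#'
#' @param fm Feature matrix (intended for at most a few hundred columns).
#' @param labels 0/1 vector.
#' @param cv_folds Number of folds (default 5).
#' @param seed Random seed (fold assignment is fixed across subset sizes).
#' @param nrounds,params Boosting rounds and extra parameters.
#' @param recorder Optional [label_access_recorder()].
#' @return List with `features` (final list), `trace` (data frame: size,
#'   mean CV accuracy, SE, feature dropped next) and `stage`.
#' @export
rfecv_select <- function(fm, labels, cv_folds = 5L, seed = 1L,
                         nrounds = 30L, params = list(max_depth = 4),
                         recorder = NULL) {
  stopifnot(is.matrix(fm), nrow(fm) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes")
  if (!is.null(recorder)) record_label_access(recorder, rownames(fm))
  fold <- make_cv_folds(labels, cv_folds, seed)
  current <- colnames(fm)
  sizes <- integer(0); means <- numeric(0); ses <- numeric(0)
  subsets <- list(); drops <- character(0)
  while (length(current) >= 1L) {
    sc <- cv_score_subset(fm[, current, drop = FALSE], labels, fold,
                          nrounds, params)
    sizes <- c(sizes, length(current))
    means <- c(means, sc["mean"]); ses <- c(ses, sc["se"])
    subsets[[length(subsets) + 1L]] <- current
    if (length(current) == 1L) { drops <- c(drops, NA_character_); break }
    d <- xgboost::xgb.DMatrix(fm[, current, drop = FALSE],
                              label = labels, nthread = 1)
    booster <- xgboost::xgb.train(
      params = c(list(objective = "binary:logistic", nthread = 1, seed = 7L),
                 params),
      data = d, nrounds = nrounds, verbose = 0)
    imp <- xgboost::xgb.importance(model = booster)
    gain <- stats::setNames(rep(0, length(current)), current)
    gain[imp$Feature] <- imp$Gain
    # drop the least important; ties (e.g. several never-used features)
    # break to the last column in current order
    worst <- names(gain)[max(which(gain == min(gain)))]
    drops <- c(drops, worst)
    current <- setdiff(current, worst)
  }
  best <- max(means)
  thr <- best - ses[which.max(means)]
  ok <- which(means >= thr)
  pick <- ok[which.min(sizes[ok])]
  features <- subsets[[pick]]
  trace <- data.frame(size = sizes, cv_accuracy = means, se = ses,
                      dropped_next = drops, stringsAsFactors = FALSE)
  gone <- setdiff(colnames(fm), features)
  dropped <- data.frame(feature = gone,
                        reason = rep("eliminated by RFECV (1-SE rule)",
                                     length(gone)),
                        partner = rep(NA_character_, length(gone)),
                        value = rep(NA_real_, length(gone)),
                        stringsAsFactors = FALSE)
  list(features = features, trace = trace,
       stage = new_stage("rfecv", colnames(fm), features, dropped))
}

#' Run the full selection cascade
#'
#' Zero-variance removal, correlation filter, GEFS and RFECV in sequence,
#' collecting a `selection_report` whose stages chain exactly
#' (out-of-stage = in-of-next-stage). Deterministic given the seed.
#'
#' @param fm Labeled feature matrix.
#' @param labels 0/1 vector.
#' @param threshold Correlation cutoff (default 0.8).
#' @param gefs,rfecv Named lists of arguments forwarded to
#'   [gefs_top_features()] and [rfecv_select()].
#' @param seed Random seed.
#' @param recorder Optional [label_access_recorder()].
#' @return List with `features`, `report` (a `selection_report`), `graph`.
#' @export
run_selection_cascade <- function(fm, labels, threshold = 0.8,
                                  gefs = list(), rfecv = list(),
                                  seed = 1L, recorder = NULL) {
  s1 <- drop_zero_variance(fm)
  s2 <- correlation_filter(s1$fm, threshold = threshold)
  s3 <- do.call(gefs_top_features,
                c(list(fm = s2$fm, labels = labels, seed = seed,
                       recorder = recorder), gefs))
  s4 <- do.call(rfecv_select,
                c(list(fm = s2$fm[, s3$features, drop = FALSE],
                       labels = labels, seed = seed, recorder = recorder),
                  rfecv))
  report <- structure(list(s1$stage, s2$stage, s3$stage, s4$stage),
                      class = "selection_report")
  list(features = s4$features, report = report, graph = s3$graph)
}
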