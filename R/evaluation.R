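# Balanced-performance evaluation: the ten measures derived from binary
# confusion counts and score lists, including the normalized Matthews
# correlation coefficient and the overall performance measure (OPM).

#' Confusion counts
#'
#' TP/TN/FP/FN container. Counts may be non-integral because fold-averaged
#' cross-validation tables report mean counts per fold.
#'
#' @param TP,TN,FP,FN Non-negative counts (reals allowed).
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = as.numeric(TP), TN = as.numeric(TN),
         FP = as.numeric(FP), FN = as.numeric(FN))
  if (any(!is.finite(v)) || any(v < 0))
    stop("confusion counts must be finite and non-negative")
  if (sum(v) == 0) stop("confusion counts are all zero")
  structure(as.list(v), class = "confusion_counts")
}

#' Confusion counts from label vectors
#'
#' @param truth 0/1 vector of true labels (1 = toxin).
#' @param predicted 0/1 vector of predicted labels.
#' @return A [confusion_counts()] object.
#' @export
counts_from_predictions <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  confusion_counts(TP = sum(truth == 1 & predicted == 1),
                   TN = sum(truth == 0 & predicted == 0),
                   FP = sum(truth == 0 & predicted == 1),
                   FN = sum(truth == 1 & predicted == 0))
}

ratio0 <- function(num, den) if (den == 0) 0 else num / den

#' Performance measures from confusion counts
#'
#' Computes NPV, PPV, specificity, sensitivity, accuracy, MCC,
#' nMCC = (1 + MCC)/2, OPM = (NPV + PPV)(specificity + sensitivity)
#' (accuracy + nMCC)/8, and F1. Ratios with zero denominators (e.g. PPV
#' with no positive predictions) are defined as 0, as is MCC with a zero
#' denominator, so every measure stays defined; affected measures are
#' listed in the `"zero_denominator"` attribute.
#'
#' @param counts A [confusion_counts()] object.
#' @param scores Optional numeric prediction scores (for AUC).
#' @param labels Optional 0/1 truth labels matching `scores`.
#' @return A `metrics_report`: named list of the ten measures (AUC is `NA`
#'   unless scores and labels are supplied).
#' @export
metrics_from_counts <- function(counts, scores = NULL, labels = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  zerod <- character(0)
  rz <- function(num, den, what) {
    if (den == 0) { zerod <<- c(zerod, what); return(0) }
    num / den
  }
  npv <- rz(TN, TN + FN, "NPV")
  ppv <- rz(TP, TP + FP, "PPV")
  spec <- rz(TN, TN + FP, "specificity")
  sens <- rz(TP, TP + FN, "sensitivity")
  acc <- (TP + TN) / (TP + TN + FP + FN)
  mcc_den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- rz(TP * TN - FP * FN, mcc_den, "MCC")
  nmcc <- (1 + mcc) / 2
  opm <- (npv + ppv) * (spec + sens) * (acc + nmcc) / 8
  f1 <- rz(2 * ppv * sens, ppv + sens, "F1")
  auc <- NA_real_
  if (!is.null(scores) && !is.null(labels))
    auc <- auc_from_scores(scores, labels)
  structure(list(NPV = npv, PPV = ppv, specificity = spec,
                 sensitivity = sens, accuracy = acc, MCC = mcc,
                 nMCC = nmcc, OPM = opm, F1 = f1, AUC = auc),
            zero_denominator = zerod,
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  v <- unlist(x)
  cat("<metrics_report>\n")
  for (n in names(v))
    cat(sprintf("  %-12s %s\n", n,
                ifelse(is.na(v[n]), "NA", format(round_half_up(v[n], digits),
                                                 nsmall = digits))))
  invisible(x)
}

#' Area under the ROC curve from scores
#'
#' Rank-based AUC equal to the Mann-Whitney U statistic normalized by
#' `n_pos * n_neg`; tied scores contribute 1/2.
#'
#' @param scores Numeric prediction scores (higher = more toxin-like).
#' @param labels 0/1 truth labels (1 = toxin).
#' @return AUC in \[0, 1\].
#' @export
auc_from_scores <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Round half away from zero
#'
#' Display rounding matching conventional table formatting (0.0005 rounds
#' up), unlike R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Method comparison table
#'
#' One row per method with confusion counts and the ten measures rounded
#' half-up to 3 decimals, plus a coverage column (fraction of inputs for
#' which the method produced a prediction).
#'
#' @param entries Named list; each element a list with `counts`
#'   (a [confusion_counts()]), optional `scores`/`labels`, optional
#'   `coverage`.
#' @return Data frame, one row per method.
#' @export
compare_table <- function(entries) {
  if (length(entries) == 0L) stop("compare_table needs at least one entry")
  rows <- lapply(names(entries), function(nm) {
    e <- entries[[nm]]
    m <- metrics_from_counts(e$counts, e$scores, e$labels)
    data.frame(method = nm,
               TP = e$counts$TP, TN = e$counts$TN,
               FP = e$counts$FP, FN = e$counts$FN,
               NPV = round_half_up(m$NPV), PPV = round_half_up(m$PPV),
               specificity = round_half_up(m$specificity),
               sensitivity = round_half_up(m$sensitivity),
               accuracy = round_half_up(m$accuracy),
               MCC = round_half_up(m$MCC), nMCC = round_half_up(m$nMCC),
               OPM = round_half_up(m$OPM), F1 = round_half_up(m$F1),
               AUC = if (is.na(m$AUC)) NA_real_ else round_half_up(m$AUC),
               coverage = if (is.null(e$coverage)) 1 else e$coverage,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Published blind-test comparison counts
#'
#' Confusion counts reported for eight protein-toxicity predictors on a
#' shared blind test set (279 toxins / 474 non-toxins), shipped as an
#' evaluation fixture so the metric arithmetic can be audited end to end.
#'
#' @return Data frame with columns `method`, `TP`, `TN`, `FP`, `FN`,
#'   `coverage`.
#' @export
blind_test_counts <- function() {
  path <- system.file("extdata", "blind_test_counts.tsv",
                      package = "toxscreen")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
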