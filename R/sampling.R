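# Clustering-based negative sampling: k-means over the negative pool in
# feature space, elbow-based selection of k, and per-cluster proportional
# sampling, so the balanced training set also covers rare sequence types.

#' Fit k-means to a feature matrix
#'
#' Best-of-restarts k-means (Lloyd's algorithm via `stats::kmeans`) on
#' z-score standardized features (constant columns are left unscaled);
#' deterministic for a fixed seed.
#'
#' @param fm Numeric feature matrix (rows = sequences).
#' @param k Number of clusters (1 <= k <= rows).
#' @param seed Random seed.
#' @param restarts Number of random restarts (default 10).
#' @param scale. Standardize columns before clustering (default TRUE).
#' @return A `cluster_model`: list with `k`, `centroids`, `assignments`
#'   (named by row id), `sse` (total within-cluster sum of squares) and
#'   `sizes`.
#' @export
kmeans_fit <- function(fm, k, seed = 1L, restarts = 10L, scale. = TRUE) {
  stopifnot(is.matrix(fm) || is.data.frame(fm))
  fm <- as.matrix(fm)
  if (k < 1L || k > nrow(fm))
    stop(sprintf("k = %d must be between 1 and nrow(fm) = %d", k, nrow(fm)))
  x <- fm
  if (isTRUE(scale.)) {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0 | is.na(sds)] <- 1
    x <- scale(x, center = TRUE, scale = sds)
  }
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100L,
                      algorithm = "Lloyd")
  ids <- rownames(fm)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(fm)))
  structure(list(k = k,
                 centroids = km$centers,
                 assignments = stats::setNames(km$cluster, ids),
                 sse = km$tot.withinss,
                 sizes = as.integer(km$size)),
            class = "cluster_model")
}

#' SSE curve over a range of k
#'
#' Fits [kmeans_fit()] for each k and collects the total within-cluster sum
#' of squared errors, the curve inspected by the elbow method.
#'
#' @inheritParams kmeans_fit
#' @param ks Integer vector of k values (default 2:20).
#' @return Named numeric vector of SSE values (names = k).
#' @export
sse_curve <- function(fm, ks = 2:20, seed = 1L, restarts = 10L,
                      scale. = TRUE) {
  sse <- vapply(ks, function(k)
    kmeans_fit(fm, k, seed = seed + k, restarts = restarts,
               scale. = scale.)$sse, numeric(1))
  stats::setNames(sse, ks)
}

#' Elbow selection of the number of clusters
#'
#' Automates the visual elbow rule: among interior points of the SSE curve,
#' returns the k maximizing the discrete second difference
#' `SSE(k-1) - 2 SSE(k) + SSE(k+1)` (the sharpest transition from steep
#' decline to flattening); ties break to the smallest k.
#'
#' @param sse_by_k Named numeric vector mapping consecutive k values to SSE.
#' @return The selected k (integer).
#' @export
elbow_select <- function(sse_by_k) {
  if (length(sse_by_k) < 3L)
    stop("elbow selection needs at least 3 consecutive k values")
  ks <- as.integer(names(sse_by_k))
  if (is.null(names(sse_by_k)) || any(is.na(ks)))
    stop("sse_by_k must be named by k")
  if (any(diff(ks) != 1L))
    stop("k values must be consecutive")
  s <- as.numeric(sse_by_k)
  n <- length(s)
  d2 <- s[1:(n - 2L)] - 2 * s[2:(n - 1L)] + s[3:n]
  ks[1L + which.max(d2)]
}

#' Per-cluster representative sampling
#'
#' Allocates a quota to each cluster proportional to its size
#' (largest-remainder rounding; every non-empty cluster contributes at
#' least one member when `n_total >= k`), then draws uniformly without
#' replacement within each cluster. Deterministic for a fixed seed.
#'
#' @param cm A `cluster_model` from [kmeans_fit()].
#' @param n_total Total number of representatives to draw.
#' @param seed Random seed.
#' @return Character vector of selected row ids (length `n_total`).
#' @export
sample_representatives <- function(cm, n_total, seed = 1L) {
  stopifnot(inherits(cm, "cluster_model"))
  ids <- names(cm$assignments)
  n <- length(ids)
  if (n_total > n)
    stop(sprintf("n_total = %d exceeds available rows = %d", n_total, n))
  if (n_total == n) return(ids)
  sizes <- vapply(seq_len(cm$k), function(j) sum(cm$assignments == j),
                  integer(1))
  quota <- proportional_quota(sizes, n_total)
  set.seed(seed)
  out <- character(0)
  for (j in seq_len(cm$k)) {
    members <- ids[cm$assignments == j]
    if (quota[j] > 0L)
      out <- c(out, sample(members, quota[j]))
  }
  out
}

# largest-remainder allocation with a minimum of 1 per non-empty cluster
# (when feasible) and quotas capped at cluster sizes
proportional_quota <- function(sizes, n_total) {
  k <- length(sizes)
  ideal <- n_total * sizes / sum(sizes)
  q <- floor(ideal)
  rem <- ideal - q
  left <- n_total - sum(q)
  if (left > 0L) {
    ord <- order(-rem, seq_len(k))
    bump <- ord[seq_len(left)]
    q[bump] <- q[bump] + 1L
  }
  # guarantee representation of every non-empty cluster when feasible
  if (n_total >= sum(sizes > 0L)) {
    while (any(sizes > 0L & q == 0L)) {
      need <- which(sizes > 0L & q == 0L)[1L]
      donor <- which.max(q)
      if (q[donor] <= 1L) break
      q[donor] <- q[donor] - 1L
      q[need] <- q[need] + 1L
    }
  }
  # cap at cluster sizes, redistributing overflow
  repeat {
    over <- q > sizes
    if (!any(over)) break
    excess <- sum(q[over] - sizes[over])
    q[over] <- sizes[over]
    spare <- which(q < sizes)
    ord <- spare[order(-(ideal[spare] - q[spare]))]
    i <- 1L
    while (excess > 0L && length(ord) > 0L) {
      j <- ord[((i - 1L) %% length(ord)) + 1L]
      if (q[j] < sizes[j]) {
        q[j] <- q[j] + 1L
        excess <- excess - 1L
      }
      i <- i + 1L
      if (i > 10000L) stop("quota redistribution failed")
    }
  }
  as.integer(q)
}

#' Build a balanced negative sample
#'
#' Convenience pipeline: cluster the negative pool, pick k by the elbow
#' rule, and sample `n_total` representatives proportionally per cluster.
#'
#' @inheritParams kmeans_fit
#' @param n_total Number of negatives to select.
#' @param ks Candidate k values for the elbow scan.
#' @return List with `ids` (selected row ids), `k`, `sse_curve` and the
#'   fitted `cluster_model`.
#' @export
balanced_negative_sample <- function(fm, n_total, ks = 2:20, seed = 1L,
                                     restarts = 10L) {
  ks <- ks[ks <= nrow(fm)]
  curve <- sse_curve(fm, ks = ks, seed = seed, restarts = restarts)
  k <- elbow_select(curve)
  cm <- kmeans_fit(fm, k, seed = seed + k, restarts = restarts)
  ids <- sample_representatives(cm, n_total, seed = seed)
  list(ids = ids, k = k, sse_curve = curve, model = cm)
}
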