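test_that("kmeans_fit reproduces hand-computable SSE on 1-D points", {
  x <- matrix(c(0, 10), ncol = 1, dimnames = list(c("a", "b"), "f"))
  m2 <- kmeans_fit(x, 2, seed = 1, scale. = FALSE)
  expect_equal(m2$sse, 0)
  m1 <- kmeans_fit(x, 1, seed = 1, scale. = FALSE)
  expect_equal(m1$sse, 50)  # centroid 5: 25 + 25
  expect_error(kmeans_fit(x, 3, seed = 1), "between 1 and")
})

test_that("kmeans_fit separates well-separated blobs and matches the exhaustive oracle", {
  set.seed(9)
  blob1 <- matrix(rnorm(10, 0, 0.2), ncol = 2)
  blob2 <- matrix(rnorm(10, 8, 0.2), ncol = 2)
  x <- rbind(blob1, blob2)
  rownames(x) <- paste0("p", 1:10)
  colnames(x) <- c("u", "v")
  cm <- kmeans_fit(x, 2, seed = 4, scale. = FALSE)
  expect_length(unique(cm$assignments[1:5]), 1L)
  expect_length(unique(cm$assignments[6:10]), 1L)
  expect_false(cm$assignments[1] == cm$assignments[6])
  # exhaustive-assignment oracle on small point sets
  for (seed in 1:3) {
    set.seed(seed)
    pts <- matrix(rnorm(12), 6, 2)
    for (k in 2:3) {
      fit <- kmeans_fit(pts, k, seed = seed, restarts = 20, scale. = FALSE)
      expect_equal(fit$sse, oracle_kmeans_sse(pts, k), tolerance = 1e-8)
    }
  }
})

test_that("SSE is non-increasing in k with best-of-restarts", {
  set.seed(21)
  x <- matrix(rnorm(60 * 3), 60)
  sse <- vapply(1:6, function(k)
    kmeans_fit(x, k, seed = 100, restarts = 10)$sse, numeric(1))
  expect_true(all(diff(sse) <= 1e-8))
})

test_that("elbow_select maximizes the second difference with smallest-k ties", {
  expect_equal(elbow_select(c(`1` = 100, `2` = 50, `3` = 48, `4` = 47,
                              `5` = 46)), 2L)
  # linear curve: all second differences 0, tie -> first interior k
  expect_equal(elbow_select(stats::setNames(seq(100, 60, by = -5), 2:10)), 3L)
  # constructed sharp knee at k = 8
  ks <- 2:20
  sse <- ifelse(ks <= 8, 1000 - 120 * (ks - 2), 280 - 4 * (ks - 8))
  expect_equal(elbow_select(stats::setNames(sse, ks)), 8L)
  expect_error(elbow_select(c(`2` = 10, `3` = 5)), "at least 3")
})

test_that("proportional quotas are exact, deduplicated and cluster-consistent", {
  set.seed(2)
  x <- matrix(rnorm(100 * 2), 100)
  rownames(x) <- paste0("r", 1:100)
  cm <- kmeans_fit(x, 5, seed = 3)
  ids <- sample_representatives(cm, 40, seed = 7)
  expect_length(ids, 40L)
  expect_false(any(duplicated(ids)))
  expect_true(all(ids %in% names(cm$assignments)))
  expect_identical(ids, sample_representatives(cm, 40, seed = 7))
  # n_total = rows returns everything
  expect_setequal(sample_representatives(cm, 100, seed = 1),
                  rownames(x))
  expect_error(sample_representatives(cm, 101), "exceeds")
  # hand example: cluster sizes 80/20, n = 10 -> quotas 8/2
  q <- toxscreen:::proportional_quota(c(80L, 20L), 10L)
  expect_equal(q, c(8L, 2L))
  # large-scale quota sums exactly, every non-empty cluster represented
  sizes <- c(120000L, 60000L, 30000L, 15000L, 10000L, 6000L, 4000L, 1092L)
  q <- toxscreen:::proportional_quota(sizes, 8412L)
  expect_equal(sum(q), 8412L)
  expect_true(all(q >= 1L))
  expect_true(all(q <= sizes))
})

test_that("balanced_negative_sample chains curve, elbow and sampling", {
  set.seed(31)
  x <- rbind(matrix(rnorm(80, 0, 0.3), ncol = 2),
             matrix(rnorm(80, 5, 0.3), ncol = 2),
             matrix(rnorm(80, c(0, 8), 0.3), ncol = 2))
  rownames(x) <- paste0("n", seq_len(nrow(x)))
  res <- balanced_negative_sample(x, 30, ks = 2:8, seed = 5)
  expect_length(res$ids, 30L)
  expect_true(res$k >= 2 && res$k <= 8)
  expect_length(res$sse_curve, 7L)
})
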