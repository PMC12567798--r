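test_that("zero-variance removal drops exactly the constant columns", {
  set.seed(1)
  x <- cbind(a = rnorm(30), b = rep(2, 30), c = rnorm(30))
  res <- drop_zero_variance(x)
  expect_equal(colnames(res$fm), c("a", "c"))
  expect_equal(res$stage$dropped$feature, "b")
  expect_equal(res$stage$n_in - nrow(res$stage$dropped), res$stage$n_out)
  # no constant columns: identity
  res2 <- drop_zero_variance(res$fm)
  expect_equal(res2$fm, res$fm)
  expect_equal(nrow(res2$stage$dropped), 0L)
  expect_error(drop_zero_variance(cbind(k = rep(1, 10))), "zero variance")
})

test_that("correlation filter keeps the earlier column, uses |r|, and is idempotent", {
  set.seed(2)
  base <- rnorm(200)
  x <- cbind(f1 = base, f2 = base, f3 = -base + rnorm(200, sd = 1e-6),
             f4 = rnorm(200))
  res <- correlation_filter(x, threshold = 0.8)
  expect_equal(colnames(res$fm), c("f1", "f4"))
  expect_equal(res$stage$dropped$partner, c("f1", "f1"))
  # independent noise survives at n = 1000
  set.seed(3)
  y <- cbind(g1 = rnorm(1000), g2 = rnorm(1000))
  expect_equal(ncol(correlation_filter(y)$fm), 2L)
  # idempotence and the postcondition: no surviving pair with |r| >= 0.8
  set.seed(4)
  z <- matrix(rnorm(100 * 30), 100)
  z <- cbind(z, z[, 1:5] + rnorm(100, sd = 0.01))
  colnames(z) <- sprintf("h%02d", seq_len(ncol(z)))
  r1 <- correlation_filter(z)
  C <- abs(stats::cor(r1$fm))
  diag(C) <- 0
  expect_true(all(C < 0.8))
  r2 <- correlation_filter(r1$fm)
  expect_equal(colnames(r2$fm), colnames(r1$fm))
  expect_equal(nrow(r2$stage$dropped), 0L)
})

test_that("GEFS recovers planted informative features and degrades gracefully", {
  d <- make_planted_matrix(seed = 500)
  g <- gefs_top_features(d$x, d$y, n_members = 20, member_top = 20,
                         top_k = 20, seed = 1, nrounds = 30,
                         params = list(max_depth = 3))
  expect_true(all(paste0("inf", 1:5) %in% g$features))
  # co-selection graph is symmetric with non-negative integer weights
  expect_true(isSymmetric(g$graph))
  expect_true(all(g$graph >= 0 & g$graph == round(g$graph)))
  # degenerate single-member ensemble returns that member's selection
  g1 <- gefs_top_features(d$x, d$y, n_members = 1, member_top = 10,
                          top_k = 10, seed = 1, nrounds = 30,
                          params = list(max_depth = 3))
  expect_length(g1$features, 10L)
  expect_true(all(g1$graph[g1$features, g1$features] == 1))
  # asking for more features than were ever selected warns and returns all
  expect_warning(
    gefs_top_features(d$x[, 1:6], d$y, n_members = 2, member_top = 3,
                      top_k = 100, seed = 1, nrounds = 10),
    "distinct features")
})

test_that("RFECV keeps informative features and honours the 1-SE rule", {
  d <- make_planted_matrix(seed = 600)
  xs <- d$x[, 1:55]  # 5 informative + 50 noise
  res <- rfecv_select(xs, d$y, cv_folds = 3, seed = 2, nrounds = 30,
                      params = list(max_depth = 3))
  expect_gte(sum(paste0("inf", 1:5) %in% res$features), 4L)
  # the returned subset's CV score is within 1 SE of the best
  best_i <- which.max(res$trace$cv_accuracy)
  thr <- res$trace$cv_accuracy[best_i] - res$trace$se[best_i]
  chosen <- res$trace$cv_accuracy[res$trace$size == length(res$features)]
  expect_gte(chosen, thr)
  # single feature in -> that feature out
  one <- rfecv_select(xs[, "inf1", drop = FALSE], d$y, cv_folds = 3,
                      seed = 1, nrounds = 10)
  expect_equal(one$features, "inf1")
  expect_error(rfecv_select(xs, rep(1L, nrow(xs))), "both classes")
})

test_that("the cascade chains stages with exact bookkeeping and is seed-deterministic", {
  d <- make_planted_matrix(n = 200, p_noise = 45, seed = 700)
  x <- cbind(d$x, const = rep(1, nrow(d$x)),
             dup_inf1 = d$x[, "inf1"])
  res <- run_selection_cascade(x, d$y, seed = 9,
                               gefs = list(n_members = 10, member_top = 15,
                                           top_k = 15, nrounds = 20),
                               rfecv = list(cv_folds = 3, nrounds = 20))
  stages <- unclass(res$report)
  for (s in stages)
    expect_equal(s$n_in - nrow(s$dropped), s$n_out)
  for (i in seq_len(length(stages) - 1))
    expect_equal(stages[[i]]$n_out, stages[[i + 1]]$n_in)
  expect_true("const" %in% stages[[1]]$dropped$feature)
  expect_true("dup_inf1" %in% stages[[2]]$dropped$feature)
  expect_true(all(res$features %in% colnames(x)))
  res2 <- run_selection_cascade(x, d$y, seed = 9,
                                gefs = list(n_members = 10, member_top = 15,
                                            top_k = 15, nrounds = 20),
                                rfecv = list(cv_folds = 3, nrounds = 20))
  expect_identical(res$features, res2$features)
  # report serializes to JSON
  f <- withr::local_tempfile(fileext = ".json")
  write_selection_report(res$report, f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "")))
})
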