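test_that("all four algorithm families separate an easy toy problem", {
  toy <- separable_toy()
  for (alg in c("gradient-boosting-A", "gradient-boosting-B",
                "random-forest", "support-vector")) {
    m <- train_classifier(toy$x, toy$y, algorithm = alg, nrounds = 30,
                          seed = 5)
    pr <- predict(m, toy$x)
    if (alg != "support-vector")  # svm probabilities are cv-calibrated
      expect_equal(mean(pr$label == toy$y), 1,
                   info = paste("training accuracy for", alg))
    expect_true(all(pr$probability >= 0 & pr$probability <= 1))
    expect_equal(pr$label, as.integer(pr$probability >= m$threshold))
  }
})

test_that("training is deterministic for a fixed seed and validates inputs", {
  toy <- separable_toy()
  m1 <- train_classifier(toy$x, toy$y, nrounds = 20, seed = 3)
  m2 <- train_classifier(toy$x, toy$y, nrounds = 20, seed = 3)
  probe <- separable_toy(seed = 99)$x
  expect_identical(predict(m1, probe), predict(m2, probe))
  expect_error(train_classifier(toy$x, rep(1L, nrow(toy$x))),
               "both classes")
  expect_error(train_classifier(toy$x, toy$y[-1]), "mismatch")
  expect_error(train_classifier(toy$x, toy$y, threshold = 1.5), "threshold")
})

test_that("prediction binds columns by name and reports missing features", {
  toy <- separable_toy()
  m <- train_classifier(toy$x, toy$y, nrounds = 20, seed = 3)
  shuffled <- toy$x[, rev(colnames(toy$x))]
  expect_equal(predict(m, shuffled), predict(m, toy$x))
  expect_error(predict(m, toy$x[, 1:5]), "missing feature columns: ")
  expect_error(predict(m, toy$x[, setdiff(colnames(toy$x), "C")]), "C")
})

test_that("held-out accuracy on a same-distribution toy exceeds 0.9", {
  train <- separable_toy(n_per_class = 20, seed = 1)
  test <- separable_toy(n_per_class = 20, seed = 2)
  m <- train_classifier(train$x, train$y, nrounds = 50, seed = 4)
  pr <- predict(m, test$x)
  expect_gte(mean(pr$label == test$y), 0.9)
})

test_that("cross_validate partitions into 5% validation folds and averages", {
  toy <- separable_toy(n_per_class = 20, seed = 8)  # 40 samples
  res <- cross_validate(toy$x, toy$y, scheme = cv_scheme(n_folds = 20,
                                                         seed = 2),
                        nrounds = 20)
  # each validation fold holds 2 samples (5% of 40), folds partition rows
  sizes <- table(res$fold_assignment)
  expect_true(all(sizes == 2))
  expect_length(res$fold_assignment, 40L)
  expect_setequal(names(res$fold_assignment), rownames(toy$x))
  # separable data: perfect averaged metrics
  expect_equal(res$metrics_mean$accuracy, 1)
  expect_equal(res$metrics_pooled$accuracy, 1)
  # averaged counts sum to the per-fold sample count
  expect_equal(res$mean_counts$TP + res$mean_counts$TN +
                 res$mean_counts$FP + res$mean_counts$FN, 2)
})

test_that("per-fold preprocessing is refit inside each training fold", {
  toy <- separable_toy(n_per_class = 20, seed = 8)
  seen <- list()
  pre <- function(x_tr, y_tr, rec) {
    seen[[length(seen) + 1L]] <<- rownames(x_tr)
    mu <- colMeans(x_tr); sdv <- apply(x_tr, 2, sd); sdv[sdv == 0] <- 1
    list(fm = scale(x_tr, mu, sdv),
         transform = function(x_new) scale(x_new, mu, sdv))
  }
  res <- cross_validate(toy$x, toy$y, scheme = cv_scheme(n_folds = 5,
                                                         seed = 1),
                        nrounds = 20, preprocess = pre)
  expect_length(seen, 5L)
  for (f in 1:5) {
    va <- names(res$fold_assignment)[res$fold_assignment == f]
    expect_length(intersect(seen[[f]], va), 0L)
  }
})

test_that("hyperparameter tuning is budgeted, bounded and deterministic", {
  toy <- separable_toy(n_per_class = 15, seed = 12)
  space <- list(max_depth = list(lower = 2, upper = 6, integer = TRUE),
                eta = list(lower = 0.05, upper = 0.5, log = TRUE))
  res <- tune_hyperparameters(toy$x, toy$y, search_space = space,
                              budget = 6L, n_init = 4L, cv_folds = 2L,
                              seed = 10, nrounds = 15)
  expect_equal(nrow(res$trace), 6L)
  expect_equal(res$best_score, max(res$trace$score))
  expect_true(all(res$trace$max_depth >= 2 & res$trace$max_depth <= 6))
  expect_true(all(res$trace$eta >= 0.05 & res$trace$eta <= 0.5))
  res2 <- tune_hyperparameters(toy$x, toy$y, search_space = space,
                               budget = 6L, n_init = 4L, cv_folds = 2L,
                               seed = 10, nrounds = 15)
  expect_equal(res$best_params, res2$best_params)
  expect_error(tune_hyperparameters(toy$x, toy$y, search_space = list(),
                                    budget = 5), "empty search space")
  expect_error(tune_hyperparameters(toy$x, toy$y, search_space = space,
                                    budget = 2L, n_init = 4L),
               "initial design")
})

test_that("model archives round-trip predictions exactly", {
  toy <- separable_toy()
  probe <- separable_toy(seed = 77)$x
  for (alg in c("gradient-boosting-A", "random-forest")) {
    m <- train_classifier(toy$x, toy$y, algorithm = alg, nrounds = 20,
                          seed = 6)
    dir <- file.path(withr::local_tempdir(), alg)
    save_model(m, dir)
    back <- load_model(dir)
    expect_equal(back$features, m$features)
    expect_equal(predict(back, probe)$probability,
                 predict(m, probe)$probability, tolerance = 1e-7)
  }
})
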