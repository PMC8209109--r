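test_that("zero-variance filtering drops exactly the constant columns", {
  m <- matrix(c(1, 2, 5, 5, 5, 7), nrow = 2) # columns: varying, constant, varying
  out <- remove_zero_variance(m)
  expect_equal(out$mask, c(TRUE, FALSE, TRUE))
  expect_equal(out$features, m[, c(1, 3)])
  # no constant columns: identity
  m2 <- matrix(rnorm(12), 3, 4)
  expect_equal(remove_zero_variance(m2)$features, m2)
  expect_true(all(remove_zero_variance(m2)$mask))
  expect_error(remove_zero_variance(matrix(1, 3, 2)), "constant")
})

test_that("the dummy classifier fits the training prevalence and predicts from it", {
  x <- matrix(rnorm(10 * 3), 10, 3)
  y <- rep(c("case", "control"), c(6, 4))
  model <- fit_pipeline(pipeline_config(dummy_prior(seed = 42)), x, y)
  expect_equal(unname(model$fit$prior), c(0.6, 0.4))
  # label-independent stochastic predictions: case fraction ~ prior
  big <- matrix(0, 2e5, 3)
  pred <- predict(model, big)
  se <- sqrt(0.6 * 0.4 / 2e5)
  expect_lt(abs(mean(pred == "case") - 0.6), 3 * se)
  # pure after fit: identical outputs on repeated calls
  expect_identical(predict(model, big[1:100, , drop = FALSE]),
    predict(model, big[1:100, , drop = FALSE]))
})

test_that("pipelines fit training data and enforce their preconditions", {
  x <- rbind(c(-1, 0), c(1, 0))
  m <- fit_pipeline(default_pipeline(), x, c("case", "control"))
  expect_equal(as.character(predict(m, x)), c("case", "control"))
  expect_equal(evaluate_accuracy(m, x, c("case", "control")), 1.0)
  # single-class training set is an error for discriminative classifiers
  expect_error(
    fit_pipeline(default_pipeline(), matrix(rnorm(6), 3), rep("case", 3)),
    "single class"
  )
  # but not for the prevalence dummy
  expect_silent(dm <- fit_pipeline(dummy_pipeline(), matrix(rnorm(6), 3), rep("case", 3)))
  # column mismatch at prediction time
  expect_error(predict(m, matrix(0, 1, 5)), "columns")
  # 13 of 20 correct
  x20 <- matrix(rep(c(-1, 1), each = 10), ncol = 1)
  y20 <- rep(c("case", "control"), each = 10)
  m20 <- fit_pipeline(default_pipeline(), x20, y20)
  flipped <- y20
  flipped[1:7] <- "control"
  expect_equal(evaluate_accuracy(m20, x20, flipped), 0.65)
})

test_that("F-test selection finds the informative features; reducers cap k", {
  withr::local_seed(8)
  n <- 300
  y <- rep(c("case", "control"), each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5)
  x[y == "case", c(2, 4)] <- x[y == "case", c(2, 4)] + 2 # signal in columns 2, 4
  cfg <- pipeline_config(linear_svm(), reducer_f_select(2))
  m <- fit_pipeline(cfg, x, y)
  expect_equal(m$reducer_fit$keep, c(2L, 4L))
  # k capped at available columns / training rows
  m2 <- fit_pipeline(pipeline_config(linear_svm(), reducer_f_select(50)), x, y)
  expect_equal(m2$reducer_fit$k, 5L)
  m3 <- fit_pipeline(pipeline_config(linear_svm(), reducer_pca(50)), x[1:6, ], y[c(1:3, 151:153)])
  expect_equal(m3$reducer_fit$k, 5L) # min(rows - 1, cols)
})

test_that("LOOCV separates clean clusters and exposes the majority-vote pathology", {
  coh <- well_separated_cohort(10)
  expect_equal(loocv_accuracy(default_pipeline(), coh), 1.0)
  # majority-vote baseline: in every fold the held-out subject's class is
  # the training minority, so LOOCV scores exactly zero on balanced data
  expect_equal(loocv_accuracy(pipeline_config(majority_vote()), coh), 0.0)
  expect_error(
    loocv_accuracy(default_pipeline(), subset_cohort(coh, 1L)),
    "at least 2"
  )
})

test_that("LOOCV accuracy is invariant to row permutation and global feature scaling", {
  coh <- tiny_cohort(10, 10, p = 8, target = 0.8, seed = 9)
  a <- loocv_accuracy(default_pipeline(), coh)
  perm <- withr::with_seed(5, sample(n_subjects(coh)))
  expect_identical(a, loocv_accuracy(default_pipeline(), subset_cohort(coh, perm)))
  # with standardization, multiplying all features by a positive constant
  # leaves linear-SVM predictions unchanged
  scaled <- coh
  scaled$features <- coh$features * 3.7
  expect_identical(a, loocv_accuracy(default_pipeline(), scaled))
})

test_that("fold-internal and globally fit scalers are genuinely different code paths", {
  coh <- leak_probe_cohort()
  fold <- loocv_accuracy(default_pipeline(), coh, scaler_scope = "fold")
  leaky <- loocv_accuracy(default_pipeline(), coh, scaler_scope = "global")
  expect_false(isTRUE(all.equal(fold, leaky)))
})

test_that("configuration grids enumerate, deduplicate and round-trip", {
  grid <- default_config_grid()
  expect_length(grid, 48L)
  labels <- vapply(grid, function(g) g$label, character(1))
  expect_equal(anyDuplicated(labels), 0L)
  # singleton grid
  single <- enumerate_configs(list(
    classifiers = list(list(type = "linear_svm", C = 1)),
    reducers = list(list(type = "none"))
  ))
  expect_length(single, 1L)
  # duplicates in the grid spec collapse
  dup <- enumerate_configs(list(
    classifiers = list(
      list(type = "linear_svm", C = c(1, 1)),
      list(type = "linear_svm", C = 1)
    ),
    reducers = list(list(type = "none"), list(type = "none"))
  ))
  expect_length(dup, 1L)
  expect_error(enumerate_configs(list(classifiers = list(), reducers = list())), "at least one")
  # YAML-style list serialization round-trips
  for (cfg in list(default_pipeline(), pipeline_config(rbf_svm(0.5), reducer_pca(10)),
    pipeline_config(dummy_prior(3)), pipeline_config(random_forest(100), reducer_f_select(7)))) {
    back <- config_from_list(config_to_list(cfg))
    expect_equal(back, cfg)
  }
})
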