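test_that("sampling plans validate their size grid and balance mode", {
  expect_error(sampling_plan(c(4L, 7L, 10L)), "odd")
  expect_silent(sampling_plan(c(4L, 7L, 10L), balance_mode = "near_balanced"))
  expect_error(sampling_plan(c(10L, 10L)), "increasing")
  expect_error(sampling_plan(c(2L, 4L)))
  full <- preset_plan("full-scale")
  expect_equal(unname(plan_cardinality(full)[["draws"]]), 147000)
  expect_equal(unname(plan_cardinality(full)[["loocv_fits"]]), 1000 * sum(4:150))
})

test_that("balanced subsampling draws n/2 per class, deterministically per seed", {
  coh <- tiny_cohort(50, 50, p = 2, seed = 1)
  idx <- draw_balanced_subsample(coh, 20, seed = 5)
  expect_length(idx, 20L)
  expect_equal(anyDuplicated(idx), 0L)
  expect_equal(sum(coh$labels[idx] == "case"), 10L)
  expect_identical(idx, draw_balanced_subsample(coh, 20, seed = 5))
  expect_false(identical(idx, draw_balanced_subsample(coh, 20, seed = 6)))
  # exhaustive draw includes every subject
  expect_equal(draw_balanced_subsample(coh, 100, seed = 2), 1:100)
  expect_error(draw_balanced_subsample(coh, 102, seed = 1), "exceeds")
  expect_error(draw_balanced_subsample(coh, 15, seed = 1), "odd")
  odd <- draw_balanced_subsample(coh, 15, seed = 1, balance_mode = "near_balanced")
  expect_length(odd, 15L)
  expect_true(sum(coh$labels[odd] == "case") %in% c(7L, 8L))
})

test_that("the overall-size analysis yields per-fold accuracies, reproducibly", {
  coh <- tiny_cohort(30, 30, p = 5, seed = 2)
  plan <- sampling_plan(c(6L, 10L), reps_per_n = 4, master_seed = 9)
  g <- overall_sample_size_analysis(coh, plan, dummy_pipeline())
  expect_s3_class(g, "accuracy_grid")
  expect_equal(nrow(g), 8L)
  # LOOCV accuracy at size N is a multiple of 1/N
  expect_true(all(abs(g$accuracy * g$n - round(g$accuracy * g$n)) < 1e-9))
  expect_true(all(g$accuracy >= 0 & g$accuracy <= 1))
  # bit-identical reruns
  g2 <- overall_sample_size_analysis(coh, plan, dummy_pipeline())
  expect_identical(grid_rows(g), grid_rows(g2))
  # per-(N, replicate) child streams: more replicates extend, never alter
  plan_more <- sampling_plan(c(6L, 10L), reps_per_n = 8, master_seed = 9)
  g3 <- overall_sample_size_analysis(coh, plan_more, dummy_pipeline())
  expect_identical(grid_rows(g), grid_rows(g3[g3$rep <= 4L, ]))
  # unbalanced cohorts are rejected up front
  expect_error(
    overall_sample_size_analysis(tiny_cohort(20, 10, seed = 1), plan, dummy_pipeline()),
    "balanced"
  )
})

test_that("a zero-signal cohort yields no optimistic bias under LOOCV", {
  coh <- tiny_cohort(50, 50, p = 10, target = 0.5, seed = 11)
  plan <- sampling_plan(16L, reps_per_n = 40, master_seed = 2)
  # the stochastic dummy sits exactly at chance in expectation
  gd <- overall_sample_size_analysis(coh, plan, dummy_pipeline())
  expect_lt(abs(mean(gd$accuracy) - 0.5), 3 * sd(gd$accuracy) / sqrt(nrow(gd)))
  # the SVM's leakage-free LOOCV mean never exceeds chance (it is in fact
  # slightly pessimistic at small N: each fold anti-correlates with its
  # held-out subject, the mild form of the majority-vote pathology)
  g <- overall_sample_size_analysis(coh, plan, default_pipeline())
  expect_lt(mean(g$accuracy), 0.5 + 3 * sd(g$accuracy) / sqrt(nrow(g)))
})

test_that("the training-size analysis holds one test set fixed and draws disjoint training sets", {
  coh <- tiny_cohort(30, 30, p = 4, seed = 3)
  plan <- sampling_plan(c(10L, 20L), reps_per_n = 50, master_seed = 4)
  g <- training_set_size_analysis(coh, plan, dummy_pipeline(), test_n = 40)
  pv <- attr(g, "provenance")
  expect_length(pv$test_subjects, 40L)
  # every accuracy is out of test_n predictions
  expect_true(all(g$m == 40L))
  # dummy ignores training features: accuracy ~ Binomial(test_n, 1/2) / test_n
  # at every training size
  for (n in c(10L, 20L)) {
    acc <- g$accuracy[g$n == n]
    expect_lt(abs(mean(acc) - 0.5), 4 * sqrt(0.25 / 40) / sqrt(length(acc)))
  }
  # infeasible: test set plus largest training set exceeds the cohort
  expect_error(
    training_set_size_analysis(coh, sampling_plan(c(22L)), dummy_pipeline(), test_n = 40),
    "too small"
  )
  expect_error(
    training_set_size_analysis(coh, plan, dummy_pipeline(), test_n = 41),
    "even"
  )
})

test_that("the test-size analysis freezes one classifier and matches its pool oracle", {
  # full-scale split arithmetic on a 934 + 934 cohort
  big <- generate_cohort(cohort_spec(934, 934, n_features = 2, seed = 5))
  plan1 <- sampling_plan(300L, reps_per_n = 3, master_seed = 6)
  res <- test_set_size_analysis(big, plan1, dummy_pipeline(),
    pool_n = 300, holdout_frac = 0.2
  )
  split <- attr(res$grid, "provenance")$split
  expect_equal(split$pool_per_class, 150L)
  expect_equal(split$holdout_per_class, 157L)
  expect_equal(split$train_per_class, 627L)
  # subsample of the whole pool reproduces the pool accuracy exactly
  pool_acc <- sum(res$pool$correct) / sum(res$pool$pool)
  expect_true(all(res$grid$accuracy == pool_acc))

  # replicate accuracies against the exact hypergeometric oracle
  coh <- tiny_cohort(60, 60, p = 5, target = 0.8, seed = 7)
  plan2 <- sampling_plan(c(10L, 20L, 40L), reps_per_n = 400, master_seed = 8)
  res2 <- test_set_size_analysis(coh, plan2, default_pipeline(), pool_n = 40)
  for (n in plan2$n_values) {
    mom <- pool_subsample_moments(res2$pool, n)
    acc <- res2$grid$accuracy[res2$grid$n == n]
    # n = pool_n draws the whole pool: both differences are exactly zero
    expect_lte(abs(mean(acc) - mom[["mean"]]), 4 * mom[["sd"]] / sqrt(length(acc)))
    expect_lte(abs(sd(acc) - mom[["sd"]]), 4 * mom[["sd"]] / sqrt(2 * (length(acc) - 1)))
  }
  expect_error(
    test_set_size_analysis(coh, sampling_plan(44L), default_pipeline(), pool_n = 40),
    "pool"
  )
})

test_that("configuration sweeps use independent child seeds and resume from checkpoints", {
  coh <- tiny_cohort(20, 20, p = 4, seed = 9)
  plan <- sampling_plan(c(6L, 10L), reps_per_n = 3, master_seed = 10)
  cfgs <- list(default_pipeline(), dummy_pipeline())
  sweep <- run_config_sweep(coh, plan, cfgs, "overall_loocv")
  expect_named(sweep, c("linear_svm_C1", "dummy_prior"))
  # a single-config sweep reproduces the direct call under the child plan
  direct <- overall_sample_size_analysis(
    coh, sweep_child_plan(plan, "linear_svm_C1"), default_pipeline()
  )
  expect_identical(grid_rows(sweep$linear_svm_C1), grid_rows(direct))
  # checkpointed labels are re-loaded, not recomputed
  ckpt <- withr::local_tempdir()
  run_config_sweep(coh, plan, cfgs[1], "overall_loocv", checkpoint_dir = ckpt)
  tampered <- read_accuracy_grid(file.path(ckpt, "linear_svm_C1.csv"))
  tampered$accuracy <- 0.123
  write_accuracy_grid(tampered, file.path(ckpt, "linear_svm_C1.csv"))
  again <- run_config_sweep(coh, plan, cfgs[1], "overall_loocv", checkpoint_dir = ckpt)
  expect_true(all(again$linear_svm_C1$accuracy == 0.123))
})

test_that("a dummy inside a sweep matches the binomial oracle regardless of reducer", {
  coh <- tiny_cohort(30, 30, p = 6, seed = 12)
  plan <- sampling_plan(20L, reps_per_n = 200, master_seed = 13)
  cfg <- pipeline_config(dummy_prior(), reducer_pca(3))
  g <- run_config_sweep(coh, plan, list(cfg), "overall_loocv")[[1]]
  p_oracle <- binomial_exceedance(20, 0.5, 0.7)
  p_emp <- mean(g$accuracy >= 0.7 - 1e-9)
  expect_lt(abs(p_emp - p_oracle), 4 * sqrt(p_oracle * (1 - p_oracle) / 200))
})

test_that("accuracy grids round-trip exactly through CSV with provenance", {
  coh <- tiny_cohort(20, 20, p = 3, seed = 14)
  plan <- sampling_plan(c(6L, 8L), reps_per_n = 3, master_seed = 15)
  g <- overall_sample_size_analysis(coh, plan, default_pipeline())
  path <- withr::local_tempfile(fileext = ".csv")
  write_accuracy_grid(g, path)
  back <- read_accuracy_grid(path)
  expect_identical(grid_rows(g), grid_rows(back))
  pv <- attr(back, "provenance")
  expect_equal(pv$analysis_kind, "overall_loocv")
  expect_equal(pv$config$label, "linear_svm_C1")
  expect_equal(pv$plan$master_seed, 15)
})
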