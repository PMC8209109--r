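test_that("binomial exceedance matches exact tail sums and edge cases", {
  # 60,460 / 1,048,576: sum of C(20, k) for k = 14..20 over 2^20
  expect_equal(binomial_exceedance(20, 0.5, 0.7), 60460 / 1048576, tolerance = 1e-12)
  expect_equal(binomial_exceedance(17, 0.5, 0), 1.0)
  expect_equal(binomial_exceedance(1, 0.5, 0.7), 0.5) # one Bernoulli must be all-correct
  expect_equal(binomial_exceedance(10, 0.5, 1), 0.5^10)
  # threshold exactly on an attainable accuracy is inclusive
  expect_equal(binomial_exceedance(10, 0.5, 0.5),
    sum(stats::dbinom(5:10, 10, 0.5)),
    tolerance = 1e-12
  )
})

test_that("chance-level misestimation is symmetric about 50%", {
  for (n in c(10, 20, 47, 100)) {
    k <- 0:n
    pmf <- stats::dbinom(k, n, 0.5)
    for (delta in c(0.05, 0.1, 0.2, 0.3)) {
      upper <- binomial_exceedance(n, 0.5, 0.5 + delta)
      lower <- sum(pmf[k / n <= 0.5 - delta + 1e-9]) # direct lower-tail sum
      expect_equal(upper, lower, tolerance = 1e-12)
    }
  }
})

test_that("hypergeometric subsample moments agree with the convolved pmf and simulation", {
  pool <- pool_correctness(150, 150, 92, 91)
  # frozen closed-form values (finite-population-corrected two-class variance)
  expect_equal(unname(pool_subsample_moments(pool, 100)), c(0.61, 0.039957),
    tolerance = 1e-4
  )
  expect_equal(unname(pool_subsample_moments(pool, 20)), c(0.61, 0.105717),
    tolerance = 1e-4
  )
  for (n in c(20, 100, 200)) {
    mom <- pool_subsample_moments(pool, n)
    # independent route: moments of the convolved exact pmf
    pmf <- misestimatr:::pool_subsample_pmf(pool, n)
    acc <- pmf$correct / n
    mean_pmf <- sum(acc * pmf$p)
    sd_pmf <- sqrt(sum((acc - mean_pmf)^2 * pmf$p))
    expect_equal(unname(mom[["mean"]]), mean_pmf, tolerance = 1e-12)
    expect_equal(unname(mom[["sd"]]), sd_pmf, tolerance = 1e-12)
  }
  # exhaustive draw: no sampling variability left
  full <- pool_subsample_moments(pool, 300)
  expect_equal(unname(full[["mean"]]), 183 / 300)
  expect_equal(unname(full[["sd"]]), 0)
  expect_error(pool_subsample_moments(pool, 15), "even")
  expect_error(pool_subsample_moments(pool, 302), "pool size")
})

test_that("exceedance oracle is a proper distribution and matches Monte Carlo", {
  pool <- pool_correctness(150, 150, 92, 91)
  for (n in c(10, 20, 100)) {
    pmf <- misestimatr:::pool_subsample_pmf(pool, n)
    expect_lt(abs(sum(pmf$p) - 1), 1e-12)
    expect_equal(pool_subsample_exceedance(pool, n, 0), 1.0)
  }
  perfect <- pool_correctness(30, 30, 30, 30)
  expect_equal(pool_subsample_exceedance(perfect, 10, 1), 1.0)
  # 1e5 seeded draws vs the exact convolution, three standard errors
  p_exact <- pool_subsample_exceedance(pool, 20, 0.7)
  sims <- simulate_pool_subsample(pool, 20, reps = 1e5, seed = 77)
  p_mc <- mean(sims >= 0.7 - 1e-9)
  expect_lt(abs(p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 1e5))
  # simulated moments against the closed forms, four standard errors
  mom <- pool_subsample_moments(pool, 20)
  expect_lt(abs(mean(sims) - mom[["mean"]]), 4 * mom[["sd"]] / sqrt(1e5))
  expect_lt(abs(sd(sims) - mom[["sd"]]), 4 * mom[["sd"]] / sqrt(2 * (1e5 - 1)))
})

test_that("subsample accuracy SD shrinks strictly with test-set size", {
  pool <- pool_correctness(150, 150, 92, 91)
  sds <- vapply(seq(10, 140, by = 10), function(n) {
    pool_subsample_moments(pool, n)[["sd"]]
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("Gaussian Bayes accuracy has the right limits", {
  expect_equal(bayes_accuracy(0), 0.5)
  expect_equal(bayes_accuracy(4), 0.97725, tolerance = 1e-5)
  expect_equal(bayes_accuracy(100), 1.0)
  expect_error(bayes_accuracy(-1), "nonnegative")
})

test_that("grid summaries compute per-size statistics with inclusive thresholds", {
  g <- data.frame(n = 20L, m = 20L, accuracy = c(0.4, 0.7, 0.8))
  st <- summarize_grid(g, thresholds = 0.7)
  expect_equal(st$p_ge_0.7, 2 / 3) # inclusive >=
  expect_equal(st$min, 0.4)
  expect_equal(st$max, 0.8)
  # constant replicate vector
  st2 <- summarize_grid(data.frame(n = 10L, m = 10L, accuracy = rep(0.6, 5)))
  expect_equal(st2$sd, 0)
  expect_equal(st2$min, st2$mean)
  # two-point distribution: closed-form mean and sample SD
  g3 <- data.frame(n = 20L, m = 20L, accuracy = rep(c(0.55, 0.75), each = 500))
  st3 <- summarize_grid(g3, thresholds = 0.7)
  expect_equal(st3$mean, 0.65)
  expect_equal(st3$sd, sqrt(1000 * 0.01 / 999), tolerance = 1e-10)
  expect_equal(st3$p_ge_0.7, 0.5)
  expect_equal(attr(st3, "sd_convention"), "sample")
  # exceedance is non-increasing in the threshold, and P(acc >= 0) = 1
  g4 <- data.frame(n = 20L, m = 20L, accuracy = seq(0, 1, length.out = 21))
  st4 <- summarize_grid(g4, thresholds = c(0, 0.25, 0.5, 0.75, 1))
  ex <- unlist(st4[grep("^p_ge_", names(st4))])
  expect_equal(unname(ex[1]), 1)
  expect_true(all(diff(ex) <= 0))
  # float-boundary robustness: 14/20 counts as reaching 0.7
  g5 <- data.frame(n = 20L, m = 20L, accuracy = 14 / 20)
  expect_equal(summarize_grid(g5, thresholds = 0.7)$p_ge_0.7, 1)
})
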