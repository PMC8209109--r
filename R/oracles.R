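#' Bayes accuracy of two spherical Gaussian classes
#'
#' For equal-covariance spherical Gaussian classes with equal priors whose
#' means differ by Mahalanobis distance `d`, the Bayes-optimal classifier
#' has accuracy `pnorm(d / 2)`.  Inverse of [calibrate_separation()].
#'
#' @param d Mahalanobis distance between class means, >= 0 (vectorized).
#' @return Accuracy in `[0.5, 1)`.
#' @export
#' @examples
#' bayes_accuracy(0) # chance
#' bayes_accuracy(calibrate_separation(0.61))
bayes_accuracy <- function(d) {
  if (!is.numeric(d) || any(d < 0)) stop("`d` must be nonnegative", call. = FALSE)
  stats::pnorm(d / 2)
}

# smallest correct count whose accuracy reaches tau on m predictions,
# computed so that accuracies exactly on the threshold count as exceeding it
min_correct_for_tau <- function(tau, m) {
  as.integer(ceiling(tau * m - 1e-9))
}

#' Exact exceedance probability of binomial accuracy
#'
#' For `X ~ Binomial(n, p)`, the exact probability that the accuracy `X/n`
#' is at least `tau`, by tail summation (no normal approximation).  The
#' threshold is inclusive: an accuracy exactly equal to `tau` counts, with
#' the comparison done on integer correct counts (`X >= ceiling(tau * n)`)
#' to avoid floating-point boundary errors.
#'
#' This is the sampling distribution of a chance-level (prevalence-prior)
#' classifier's estimated accuracy: each of the `n` test predictions is an
#' independent Bernoulli with success probability `p` (0.5 on balanced
#' data), so apparent accuracies well above chance arise purely by
#' sampling error, with probability given here.
#'
#' @param n Number of predictions, >= 1.
#' @param p Per-prediction success probability in `[0, 1]`.
#' @param tau Accuracy threshold in `[0, 1]` (vectorized).
#' @return `P(X/n >= tau)`.
#' @export
#' @examples
#' binomial_exceedance(20, 0.5, 0.7) # ~0.0577: 70%+ "by chance" at N = 20
#' binomial_exceedance(100, 0.5, 0.7) # ~3e-5 at N = 100
binomial_exceedance <- function(n, p, tau) {
  stopifnot(
    is.numeric(n), length(n) == 1L, n >= 1,
    is.numeric(p), length(p) == 1L, p >= 0, p <= 1,
    is.numeric(tau), all(tau >= 0), all(tau <= 1)
  )
  n <- as.integer(n)
  k <- pmax(min_correct_for_tau(tau, n), 0L)
  stats::pbinom(k - 1L, n, p, lower.tail = FALSE)
}

#' Frozen per-class correctness of a fixed classifier over a prediction pool
#'
#' Records, for one trained classifier evaluated once on a fixed balanced
#' pool of subjects, how many subjects of each class were predicted
#' correctly.  Because subsampled test-set accuracies are determined
#' entirely by which pool subjects are drawn, this small object is all the
#' analytic oracles need.
#'
#' @param n_cases,n_controls Pool size per class, >= 1.
#' @param correct_cases,correct_controls Correctly predicted subjects per
#'   class, between 0 and the class pool size.
#' @return An object of class `pool_correctness`.
#' @export
#' @examples
#' # a 300-subject pool of which 61% (92 + 91) are predicted correctly
#' pool_correctness(150, 150, 92, 91)
pool_correctness <- function(n_cases, n_controls, correct_cases, correct_controls) {
  stopifnot(
    n_cases >= 1, n_controls >= 1,
    correct_cases >= 0, correct_cases <= n_cases,
    correct_controls >= 0, correct_controls <= n_controls
  )
  structure(
    list(
      pool = c(case = as.integer(n_cases), control = as.integer(n_controls)),
      correct = c(case = as.integer(correct_cases), control = as.integer(correct_controls))
    ),
    class = "pool_correctness"
  )
}

#' @export
print.pool_correctness <- function(x, ...) {
  cat(sprintf(
    "<pool_correctness> %d/%d cases, %d/%d controls correct (pool accuracy %.4f)\n",
    x$correct[["case"]], x$pool[["case"]],
    x$correct[["control"]], x$pool[["control"]],
    sum(x$correct) / sum(x$pool)
  ))
  invisible(x)
}

check_pool_n <- function(pool, n) {
  stopifnot(inherits(pool, "pool_correctness"))
  if (n %% 2 != 0) stop("`n` must be even (n/2 per class)", call. = FALSE)
  if (n < 2 || n / 2 > min(pool$pool)) {
    stop("`n/2` must not exceed either class pool size", call. = FALSE)
  }
  as.integer(n / 2)
}

#' Exact moments of subsampled test-set accuracy
#'
#' When a balanced test set of `n` subjects (`n/2` per class) is drawn
#' without replacement from a fixed pool with frozen per-class correctness,
#' the number of correct predictions is the sum of two independent
#' hypergeometric counts.  This returns the exact mean and standard
#' deviation of the subsample accuracy, including the per-class
#' finite-population correction `(M - n/2) / (M - 1)`.
#'
#' @param pool A [pool_correctness()].
#' @param n Even subsample size with `n/2` at most each class pool size.
#' @return Named numeric vector `c(mean = ..., sd = ...)`.
#' @export
#' @examples
#' pool <- pool_correctness(150, 150, 92, 91)
#' pool_subsample_moments(pool, 100) # sd ~0.040
#' pool_subsample_moments(pool, 20) # sd ~0.106
pool_subsample_moments <- function(pool, n) {
  m <- check_pool_n(pool, n)
  M <- pool$pool
  K <- pool$correct
  pr <- K / M
  mean_acc <- sum(m * pr) / n
  fpc <- (M - m) / (M - 1)
  var_acc <- sum(m * pr * (1 - pr) * fpc) / n^2
  c(mean = mean_acc, sd = sqrt(var_acc))
}

# exact pmf of correct counts in a balanced subsample of n from the pool:
# convolution of the two per-class hypergeometric mass functions
pool_subsample_pmf <- function(pool, n) {
  m <- check_pool_n(pool, n)
  M <- pool$pool
  K <- pool$correct
  support <- function(cls) {
    lo <- max(0L, m - (M[[cls]] - K[[cls]]))
    hi <- min(m, K[[cls]])
    k <- lo:hi
    list(k = k, p = stats::dhyper(k, K[[cls]], M[[cls]] - K[[cls]], m))
  }
  s1 <- support("case")
  s2 <- support("control")
  total <- outer(s1$k, s2$k, "+")
  pr <- outer(s1$p, s2$p)
  pmf <- tapply(as.vector(pr), as.vector(total), sum)
  list(correct = as.integer(names(pmf)), p = as.vector(pmf))
}

#' Exact exceedance probability of subsampled test-set accuracy
#'
#' Exact `P(accuracy >= tau)` for a balanced without-replacement subsample
#' of `n` from a frozen pool, by convolving the two per-class
#' hypergeometric mass functions.  Thresholds are inclusive and compared on
#' integer correct counts.
#'
#' @inheritParams pool_subsample_moments
#' @param tau Accuracy threshold in `[0, 1]` (vectorized).
#' @return `P(accuracy >= tau)`.
#' @export
#' @examples
#' pool <- pool_correctness(150, 150, 92, 91)
#' pool_subsample_exceedance(pool, 20, 0.7)
#' pool_subsample_exceedance(pool, 100, 0.7)
pool_subsample_exceedance <- function(pool, n, tau) {
  stopifnot(is.numeric(tau), all(tau >= 0), all(tau <= 1))
  pmf <- pool_subsample_pmf(pool, n)
  vapply(tau, function(t) {
    sum(pmf$p[pmf$correct >= min_correct_for_tau(t, n)])
  }, numeric(1))
}

#' Simulate balanced subsampling from a frozen prediction pool
#'
#' Monte-Carlo counterpart of [pool_subsample_moments()] /
#' [pool_subsample_exceedance()]: repeatedly draws `n/2` subjects per class
#' without replacement from the pool's correctness vectors and records the
#' subsample accuracy.  Draws are independent across replicates (subjects
#' may recur between replicates).
#'
#' @inheritParams pool_subsample_moments
#' @param reps Number of replicate subsamples.
#' @param seed Integer seed.
#' @return Numeric vector of `reps` accuracies.
#' @export
#' @examples
#' pool <- pool_correctness(150, 150, 92, 91)
#' sd(simulate_pool_subsample(pool, 100, reps = 1000, seed = 1))
simulate_pool_subsample <- function(pool, n, reps, seed = 1L) {
  m <- check_pool_n(pool, n)
  M <- pool$pool
  K <- pool$correct
  corr_case <- rep(c(1L, 0L), c(K[["case"]], M[["case"]] - K[["case"]]))
  corr_ctrl <- rep(c(1L, 0L), c(K[["control"]], M[["control"]] - K[["control"]]))
  withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      (sum(corr_case[sample.int(M[["case"]], m)]) +
        sum(corr_ctrl[sample.int(M[["control"]], m)])) / n
    }, numeric(1))
  })
}
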