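# Small cohorts and crafted datasets shared across test files.

tiny_cohort <- function(n_cases = 30L, n_controls = 30L, p = 5L,
                        target = 0.61, seed = 1L, sites = 1L, site_scale = 0) {
  generate_cohort(cohort_spec(
    n_cases = n_cases, n_controls = n_controls, n_features = p,
    target_bayes_accuracy = target, n_sites = sites,
    site_shift_scale = site_scale, seed = seed
  ))
}

# two clusters with a margin far exceeding the noise: every LOOCV fold
# separates perfectly
well_separated_cohort <- function(n_per_class = 10L, p = 4L, seed = 3L) {
  withr::with_seed(seed, {
    n <- 2L * n_per_class
    labels <- rep(c("case", "control"), each = n_per_class)
    x <- matrix(rnorm(n * p, sd = 0.1), n, p)
    x[labels == "case", ] <- x[labels == "case", ] + 5
    misestimatr:::new_cohort(x, labels, rep(1L, n), sprintf("W%03d", seq_len(n)))
  })
}

# weak-signal dataset with two extreme outlier entries: fold-internal and
# globally fit scalers give measurably different LOOCV accuracies
leak_probe_cohort <- function() {
  withr::with_seed(2, {
    n <- 12L
    labels <- rep(c("case", "control"), each = 6L)
    x <- cbind(
      rep(c(2, -2), each = 6L) + rnorm(n),
      rnorm(n), rnorm(n), rnorm(n)
    )
    x[1L, 2L] <- 50
    x[7L, 3L] <- -50
    misestimatr:::new_cohort(x, labels, rep(1L, n), sprintf("L%03d", seq_len(n)))
  })
}

dummy_pipeline <- function() {
  pipeline_config(dummy_prior(), standardize = FALSE)
}

# the replicate rows of a grid, stripped of class and provenance, for
# identity comparisons
grid_rows <- function(g) {
  df <- tibble::as_tibble(g)
  attr(df, "provenance") <- NULL
  class(df) <- c("tbl_df", "tbl", "data.frame")
  df
}
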