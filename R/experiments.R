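#' Sampling plan for a sample-size experiment
#'
#' Fixes the grid of sample sizes, the number of replicate subsamples per
#' size, how odd sizes are handled, and the master seed from which every
#' replicate's random stream is derived.
#'
#' @param n_values Strictly increasing sample sizes, each >= 4.  Default:
#'   even sizes 4 to 150, a desk-scale version of a size-1-step grid from 4
#'   to 150.
#' @param reps_per_n Replicate subsamples per size (>= 1).  Default 100;
#'   a full-scale study would use 1000.
#' @param balance_mode `"even_only"` (default): only literally balanced
#'   subsamples are allowed and odd `n_values` are rejected at validation.
#'   `"near_balanced"`: odd sizes are allowed; the extra subject's class is
#'   chosen by a seeded coin flip per replicate.
#' @param master_seed Integer master seed.
#' @return An object of class `sampling_plan`.
#' @seealso [preset_plan()] for the desk and full-scale presets.
#' @export
#' @examples
#' sampling_plan(n_values = c(10, 20, 50), reps_per_n = 25)
sampling_plan <- function(n_values = seq(4L, 150L, by = 2L),
                          reps_per_n = 100L,
                          balance_mode = c("even_only", "near_balanced"),
                          master_seed = 1L) {
  balance_mode <- match.arg(balance_mode)
  n_values <- as.integer(n_values)
  stopifnot(
    length(n_values) >= 1, all(n_values >= 4),
    length(reps_per_n) == 1L, reps_per_n >= 1,
    length(master_seed) == 1L, is.finite(master_seed)
  )
  if (is.unsorted(n_values, strictly = TRUE)) {
    stop("`n_values` must be strictly increasing", call. = FALSE)
  }
  if (balance_mode == "even_only" && any(n_values %% 2L != 0L)) {
    stop("odd n_values are not allowed under balance_mode = 'even_only'",
      call. = FALSE
    )
  }
  structure(
    list(
      n_values = n_values,
      reps_per_n = as.integer(reps_per_n),
      balance_mode = balance_mode,
      master_seed = as.integer(master_seed)
    ),
    class = "sampling_plan"
  )
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf(
    "<sampling_plan> %d sizes in [%d, %d], %d reps each (%s), master seed %d\n",
    length(x$n_values), min(x$n_values), max(x$n_values),
    x$reps_per_n, x$balance_mode, x$master_seed
  ))
  invisible(x)
}

#' Preset sampling plans
#'
#' `"desk"`: even sizes 4–150, 100 replicates each — runs in minutes on one
#' CPU and reproduces every qualitative effect.  `"full-scale"`: sizes 4–150
#' in steps of 1 (near-balanced mode for odd sizes), 1000 replicates each —
#' the 147,000-subsample design of a full study; expect millions of model
#' fits in the overall-size analysis.
#'
#' @param preset `"desk"` or `"full-scale"`.
#' @param master_seed Integer master seed.
#' @return A [sampling_plan()].
#' @export
preset_plan <- function(preset = c("desk", "full-scale"), master_seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    "desk" = sampling_plan(seq(4L, 150L, 2L), 100L, "even_only", master_seed),
    "full-scale" = sampling_plan(4L:150L, 1000L, "near_balanced", master_seed)
  )
}

#' Total subsample draws in a plan
#'
#' The number of (size, replicate) subsample draws a plan generates:
#' `length(n_values) * reps_per_n`.  For the full-scale plan (sizes 4–150
#' step 1, 1000 replicates) this is 147,000.  The number of model fits in
#' the overall-size (LOOCV) analysis is `reps_per_n * sum(n_values)`.
#'
#' @param plan A [sampling_plan()].
#' @return Named numeric vector `c(draws = ..., loocv_fits = ...)`.
#' @export
#' @examples
#' plan_cardinality(preset_plan("full-scale"))
plan_cardinality <- function(plan) {
  stopifnot(inherits(plan, "sampling_plan"))
  c(
    draws = length(plan$n_values) * plan$reps_per_n,
    loocv_fits = plan$reps_per_n * sum(plan$n_values)
  )
}

# Counter-based child-seed derivation: master seed -> per-analysis stream ->
# per-(n, replicate) substream.  Pure arithmetic, so parallel or resumed
# execution cannot reorder randomness.  All intermediates stay below 2^53;
# the result is a valid 32-bit seed.
derive_seed <- function(master, stream, n = 0L, rep = 0L) {
  h <- (abs(as.numeric(master)) * 48271 +
    as.numeric(stream) * 1299721 +
    as.numeric(n) * 7919 +
    as.numeric(rep) * 104729) %% 2147483629
  as.integer(h) + 1L
}

label_stream <- function(label) {
  # deterministic small-integer stream id from a config label
  sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 100000L
}

# draw a balanced (or near-balanced) subsample using the ambient RNG stream
draw_balanced <- function(cohort, n, balance_mode = "even_only") {
  cc <- class_counts(cohort)
  if (n > 2L * min(cc)) {
    stop(sprintf("n = %d exceeds twice the minority class size (%d)", n, min(cc)),
      call. = FALSE
    )
  }
  if (n %% 2L == 0L) {
    n_case <- n %/% 2L
  } else {
    if (balance_mode == "even_only") {
      stop("odd n requires balance_mode = 'near_balanced'", call. = FALSE)
    }
    n_case <- n %/% 2L + stats::rbinom(1L, 1L, 0.5)
  }
  n_ctrl <- n - n_case
  idx_case <- which(cohort$labels == "case")
  idx_ctrl <- which(cohort$labels == "control")
  if (n_case > length(idx_case) || n_ctrl > length(idx_ctrl)) {
    stop("subsample exceeds a class size", call. = FALSE)
  }
  sort(c(sample(idx_case, n_case), sample(idx_ctrl, n_ctrl)))
}

#' Draw one balanced subsample of a cohort
#'
#' Samples `n/2` cases and `n/2` controls uniformly without replacement
#' (under `"near_balanced"`, odd `n` assigns the extra subject's class by a
#' seeded coin flip).  Deterministic given `(cohort, n, seed)`; draws with
#' different seeds are independent and may overlap.
#'
#' @param cohort A `cohort`.
#' @param n Subsample size, at most twice the minority class size.
#' @param seed Integer seed.
#' @param balance_mode `"even_only"` or `"near_balanced"`.
#' @return Sorted integer vector of subject indices.
#' @export
draw_balanced_subsample <- function(cohort, n, seed, balance_mode = "even_only") {
  stopifnot(inherits(cohort, "cohort"))
  withr::with_seed(seed, draw_balanced(cohort, n, balance_mode))
}

cohort_fingerprint <- function(cohort) {
  cc <- class_counts(cohort)
  list(
    n_cases = unname(cc[["case"]]), n_controls = unname(cc[["control"]]),
    n_features = ncol(cohort$features),
    feature_checksum = signif(sum(cohort$features), 12)
  )
}

new_accuracy_grid <- function(df, analysis_kind, config, plan, cohort, extra = list()) {
  grid <- tibble::as_tibble(df)
  provenance <- c(
    list(
      analysis_kind = analysis_kind,
      config = config_to_list(config),
      plan = unclass(plan),
      cohort = cohort_fingerprint(cohort)
    ),
    extra
  )
  structure(grid,
    class = c("accuracy_grid", class(grid)),
    provenance = provenance
  )
}

#' @export
print.accuracy_grid <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat(sprintf(
    "<accuracy_grid> %s | %s | %d sizes x %d reps\n",
    pv$analysis_kind, pv$config$label,
    length(unique(x$n)), max(x$rep)
  ))
  NextMethod()
}

require_balanced <- function(cohort) {
  if (!is_balanced(cohort)) {
    stop("cohort must be balanced; apply random_undersample() first", call. = FALSE)
  }
}

#' Overall sample-size analysis (LOOCV)
#'
#' The first experiment: for every size `N` in the plan and every
#' replicate, draw a fresh balanced subsample of the cohort and estimate
#' accuracy by leave-one-out cross-validation of the pipeline on that
#' subsample alone — the design of a small study that uses all of its `N`
#' subjects for both training and testing.  The spread of the resulting
#' per-`N` accuracy distributions is the misestimation risk at that study
#' size.
#'
#' @param cohort A balanced `cohort` (apply [random_undersample()] first).
#' @param plan A [sampling_plan()].
#' @param config A [pipeline_config()].
#' @return An `accuracy_grid`: tibble with columns `analysis`,
#'   `config_label`, `n`, `rep`, `seed`, `m` (number of evaluated
#'   predictions, here `n`) and `accuracy`, plus a `provenance` attribute
#'   recording config, plan, cohort fingerprint and total fit count.
#' @export
overall_sample_size_analysis <- function(cohort, plan, config) {
  stopifnot(inherits(cohort, "cohort"), inherits(plan, "sampling_plan"),
    inherits(config, "pipeline_config"))
  require_balanced(cohort)
  rows <- expand.grid(rep = seq_len(plan$reps_per_n), n = plan$n_values)
  seeds <- mapply(derive_seed,
    n = rows$n, rep = rows$rep,
    MoreArgs = list(master = plan$master_seed, stream = 1L)
  )
  acc <- vapply(seq_len(nrow(rows)), function(i) {
    withr::with_seed(seeds[i], {
      idx <- draw_balanced(cohort, rows$n[i], plan$balance_mode)
      loocv_accuracy(config, subset_cohort(cohort, idx))
    })
  }, numeric(1))
  new_accuracy_grid(
    data.frame(
      analysis = "overall_loocv", config_label = config$label,
      n = rows$n, rep = rows$rep, seed = seeds, m = rows$n, accuracy = acc
    ),
    "overall_loocv", config, plan, cohort,
    extra = list(n_fits = sum(rows$n))
  )
}

#' Training-set-size analysis (fixed large test set)
#'
#' The second experiment: one balanced test set of `test_n` subjects is
#' drawn once and held fixed; for every `(N, replicate)` a balanced
#' training set disjoint from the test set is drawn, the pipeline is fit on
#' it, and accuracy is measured on the fixed test set.  Isolates the effect
#' of training-set size from test-set sampling error.
#'
#' @inheritParams overall_sample_size_analysis
#' @param test_n Size of the fixed balanced test set (default 300).
#' @return An `accuracy_grid` (see [overall_sample_size_analysis()]); `m`
#'   is `test_n` for every row.  The provenance records the test-set
#'   subject ids.
#' @export
training_set_size_analysis <- function(cohort, plan, config, test_n = 300L) {
  stopifnot(inherits(cohort, "cohort"), inherits(plan, "sampling_plan"),
    inherits(config, "pipeline_config"))
  require_balanced(cohort)
  cc <- class_counts(cohort)
  if (test_n %% 2L != 0L) stop("`test_n` must be even", call. = FALSE)
  if (test_n / 2 + ceiling(max(plan$n_values) / 2) > min(cc)) {
    stop("cohort too small for a disjoint test set plus the largest training set",
      call. = FALSE
    )
  }
  test_idx <- draw_balanced_subsample(cohort, test_n,
    seed = derive_seed(plan$master_seed, 2L, 0L, 0L)
  )
  test <- subset_cohort(cohort, test_idx)
  remainder <- subset_cohort(cohort, -test_idx)

  rows <- expand.grid(rep = seq_len(plan$reps_per_n), n = plan$n_values)
  seeds <- mapply(derive_seed,
    n = rows$n, rep = rows$rep,
    MoreArgs = list(master = plan$master_seed, stream = 2L)
  )
  acc <- vapply(seq_len(nrow(rows)), function(i) {
    withr::with_seed(seeds[i], {
      idx <- draw_balanced(remainder, rows$n[i], plan$balance_mode)
      train <- subset_cohort(remainder, idx)
      model <- fit_pipeline(config, train$features, train$labels)
      evaluate_accuracy(model, test$features, test$labels)
    })
  }, numeric(1))
  new_accuracy_grid(
    data.frame(
      analysis = "train_size", config_label = config$label,
      n = rows$n, rep = rows$rep, seed = seeds, m = test_n, accuracy = acc
    ),
    "train_size", config, plan, cohort,
    extra = list(
      test_n = test_n, test_subjects = test$subject_ids,
      n_fits = nrow(rows)
    )
  )
}

#' Test-set-size analysis (one fixed classifier)
#'
#' The third experiment isolates test-set sampling error.  A balanced
#' prediction pool of `pool_n` subjects is drawn once; from the remaining
#' subjects a balanced holdout of `holdout_frac` per class is set aside,
#' and a single model is trained on everything else.  The model's
#' per-subject correctness over the pool is frozen; for every
#' `(N, replicate)` a balanced subsample of the pool is drawn and its
#' accuracy computed from the frozen correctness, so every accuracy in the
#' grid comes from the same fixed classifier and differs only by which test
#' subjects were drawn.
#'
#' With the default sizes on a 934 + 934 cohort the partition is
#' 150 + 150 (pool) / 157 + 157 (holdout) / 627 + 627 (training).
#'
#' @inheritParams overall_sample_size_analysis
#' @param pool_n Size of the balanced prediction pool (default 300).
#' @param holdout_frac Fraction of each remaining class set aside as a
#'   large holdout, whose accuracy is reported as a reliable reference
#'   (default 0.2).
#' @return A list of class `test_size_result` with elements `grid` (an
#'   `accuracy_grid`; `m` is `n` for every row), `holdout_accuracy`, and
#'   `pool` (a [pool_correctness()] — the input to the analytic
#'   hypergeometric oracles).
#' @export
test_set_size_analysis <- function(cohort, plan, config, pool_n = 300L,
                                   holdout_frac = 0.2) {
  stopifnot(inherits(cohort, "cohort"), inherits(plan, "sampling_plan"),
    inherits(config, "pipeline_config"))
  require_balanced(cohort)
  if (pool_n %% 2L != 0L) stop("`pool_n` must be even", call. = FALSE)
  if (max(plan$n_values) > pool_n) {
    stop("largest test size exceeds the pool size", call. = FALSE)
  }
  cc <- class_counts(cohort)
  m_class <- min(cc)
  pool_per_class <- pool_n %/% 2L
  rem_per_class <- m_class - pool_per_class
  hold_per_class <- round(holdout_frac * rem_per_class)
  train_per_class <- rem_per_class - hold_per_class
  if (train_per_class < 1L || hold_per_class < 1L) {
    stop("cohort too small for pool + holdout + training split", call. = FALSE)
  }

  pool_idx <- draw_balanced_subsample(cohort, pool_n,
    seed = derive_seed(plan$master_seed, 3L, 0L, 1L)
  )
  pool_cohort <- subset_cohort(cohort, pool_idx)
  remainder <- subset_cohort(cohort, -pool_idx)
  hold_idx <- draw_balanced_subsample(remainder, 2L * hold_per_class,
    seed = derive_seed(plan$master_seed, 3L, 0L, 2L)
  )
  holdout <- subset_cohort(remainder, hold_idx)
  train <- subset_cohort(remainder, -hold_idx)

  model <- withr::with_seed(
    derive_seed(plan$master_seed, 3L, 0L, 3L),
    fit_pipeline(config, train$features, train$labels)
  )
  pool_pred <- predict(model, pool_cohort$features)
  pool_correct <- pool_pred == pool_cohort$labels
  is_case <- pool_cohort$labels == "case"
  pool <- pool_correctness(
    sum(is_case), sum(!is_case),
    sum(pool_correct[is_case]), sum(pool_correct[!is_case])
  )
  holdout_accuracy <- evaluate_accuracy(model, holdout$features, holdout$labels)

  corr_case <- pool_correct[is_case]
  corr_ctrl <- pool_correct[!is_case]
  rows <- expand.grid(rep = seq_len(plan$reps_per_n), n = plan$n_values)
  seeds <- mapply(derive_seed,
    n = rows$n, rep = rows$rep,
    MoreArgs = list(master = plan$master_seed, stream = 3L)
  )
  acc <- vapply(seq_len(nrow(rows)), function(i) {
    n <- rows$n[i]
    withr::with_seed(seeds[i], {
      if (n %% 2L == 0L) {
        n_case <- n %/% 2L
      } else {
        if (plan$balance_mode == "even_only") {
          stop("odd n requires balance_mode = 'near_balanced'", call. = FALSE)
        }
        n_case <- n %/% 2L + stats::rbinom(1L, 1L, 0.5)
      }
      (sum(corr_case[sample.int(length(corr_case), n_case)]) +
        sum(corr_ctrl[sample.int(length(corr_ctrl), n - n_case)])) / n
    })
  }, numeric(1))
  grid <- new_accuracy_grid(
    data.frame(
      analysis = "test_size", config_label = config$label,
      n = rows$n, rep = rows$rep, seed = seeds, m = rows$n, accuracy = acc
    ),
    "test_size", config, plan, cohort,
    extra = list(
      pool_n = pool_n, holdout_frac = holdout_frac,
      split = list(
        pool_per_class = pool_per_class,
        holdout_per_class = hold_per_class,
        train_per_class = train_per_class
      ),
      pool = list(pool = as.list(pool$pool), correct = as.list(pool$correct)),
      holdout_accuracy = holdout_accuracy, n_fits = 1L
    )
  )
  structure(
    list(grid = grid, holdout_accuracy = holdout_accuracy, pool = pool),
    class = "test_size_result"
  )
}

#' @export
print.test_size_result <- function(x, ...) {
  cat(sprintf("<test_size_result> holdout accuracy %.4f\n", x$holdout_accuracy))
  print(x$pool)
  invisible(x)
}

#' Child sampling plan for one configuration of a sweep
#'
#' Derives the per-configuration master seed a [run_config_sweep()] uses,
#' so a sweep over a single configuration is reproducible by a direct call
#' to the analysis with this plan.
#'
#' @param plan A [sampling_plan()].
#' @param label Configuration label.
#' @return A [sampling_plan()] with a config-specific master seed.
#' @export
sweep_child_plan <- function(plan, label) {
  stopifnot(inherits(plan, "sampling_plan"))
  sampling_plan(plan$n_values, plan$reps_per_n, plan$balance_mode,
    master_seed = derive_seed(plan$master_seed, 10L + label_stream(label))
  )
}

#' Run one analysis over a list of pipeline configurations
#'
#' Applies the chosen sample-size analysis to every configuration, with
#' independent child seeds per configuration (see [sweep_child_plan()]).
#' When `checkpoint_dir` is given each configuration's grid is written to
#' `<label>.csv` there as it completes, and already-present labels are
#' re-loaded instead of re-run, making long sweeps resumable.
#'
#' @inheritParams overall_sample_size_analysis
#' @param configs Nonempty list of [pipeline_config()]s.
#' @param analysis Which analysis to run.
#' @param checkpoint_dir Optional directory for resumable per-config grids.
#' @param ... Passed to the analysis function (e.g. `test_n`, `pool_n`).
#' @return Named list of `accuracy_grid`s keyed by configuration label
#'   (for `"test_size"`, the grid component of each result).
#' @export
run_config_sweep <- function(cohort, plan, configs,
                             analysis = c("overall_loocv", "train_size", "test_size"),
                             checkpoint_dir = NULL, ...) {
  analysis <- match.arg(analysis)
  if (!is.list(configs) || length(configs) == 0L) {
    stop("`configs` must be a nonempty list of pipeline_config objects", call. = FALSE)
  }
  fun <- switch(analysis,
    overall_loocv = overall_sample_size_analysis,
    train_size = training_set_size_analysis,
    test_size = function(cohort, plan, config, ...) {
      test_set_size_analysis(cohort, plan, config, ...)$grid
    }
  )
  out <- list()
  for (config in configs) {
    label <- config$label
    ckpt <- if (!is.null(checkpoint_dir)) file.path(checkpoint_dir, paste0(label, ".csv"))
    if (!is.null(ckpt) && file.exists(ckpt)) {
      out[[label]] <- read_accuracy_grid(ckpt)
      next
    }
    grid <- fun(cohort, sweep_child_plan(plan, label), config, ...)
    if (!is.null(ckpt)) {
      dir.create(dirname(ckpt), recursive = TRUE, showWarnings = FALSE)
      write_accuracy_grid(grid, ckpt)
    }
    out[[label]] <- grid
  }
  out
}

#' Persist and re-load accuracy grids
#'
#' Grids are written as tidy CSV (columns `analysis`, `config_label`, `n`,
#' `rep`, `seed`, `m`, `accuracy`) with a JSON provenance sidecar at
#' `<path>.json`; accuracies use shortest round-trip doubles so re-loading
#' reproduces the grid exactly.
#'
#' @param grid An `accuracy_grid`.
#' @param path CSV file path.
#' @return `write_accuracy_grid()` returns `path` invisibly;
#'   `read_accuracy_grid()` returns the `accuracy_grid`.
#' @export
write_accuracy_grid <- function(grid, path) {
  stopifnot(inherits(grid, "accuracy_grid"))
  out <- as.data.frame(grid)
  out$accuracy <- sprintf("%.17g", out$accuracy) # exact double round trip
  readr::write_csv(out, path, progress = FALSE)
  jsonlite::write_json(attr(grid, "provenance"), paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_accuracy_grid
#' @export
read_accuracy_grid <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(
      analysis = readr::col_character(),
      config_label = readr::col_character(),
      n = readr::col_integer(),
      rep = readr::col_integer(),
      seed = readr::col_integer(),
      m = readr::col_integer(),
      accuracy = readr::col_character()
    ),
    progress = FALSE
  )
  df$accuracy <- as.numeric(df$accuracy) # correctly rounded: exact round trip
  df <- tibble::as_tibble(df)
  sidecar <- paste0(path, ".json")
  provenance <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
  structure(df, class = c("accuracy_grid", class(df)), provenance = provenance)
}
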