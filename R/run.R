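#' Configuration of a reproducible end-to-end run
#'
#' Bundles everything a run needs — cohort source, sampling plan, pipeline
#' configurations, analyses, output directory and master seed — into one
#' serializable object.  A persisted run configuration re-executes to
#' bit-identical outputs with the same package version.
#'
#' @param cohort A [cohort_spec()] (the cohort is generated) or a file path
#'   to a delimited-text cohort (see [read_cohort()]).
#' @param plan A [sampling_plan()].
#' @param configs List of [pipeline_config()]s to run.  Default: the
#'   study's default linear-SVM pipeline plus its dummy-prior mirror.
#' @param analyses Subset of
#'   `c("overall_loocv", "train_size", "test_size")`.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed for the whole run.
#' @param test_n,pool_n,holdout_frac Sizes for the training-set and
#'   test-set analyses (see [training_set_size_analysis()] and
#'   [test_set_size_analysis()]).
#' @param figures Write a four-panel figure per analysis (requires ggplot2
#'   and patchwork; silently skipped when unavailable — CSV/JSON are the
#'   canonical outputs).
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       plan = preset_plan("desk"),
                       configs = list(
                         default_pipeline(),
                         pipeline_config(dummy_prior())
                       ),
                       analyses = c("overall_loocv", "train_size", "test_size"),
                       out_dir = "misestimatr-run",
                       seed = 1L,
                       test_n = 300L, pool_n = 300L, holdout_frac = 0.2,
                       figures = FALSE) {
  stopifnot(
    inherits(cohort, "cohort_spec") || (is.character(cohort) && length(cohort) == 1L),
    inherits(plan, "sampling_plan"),
    is.list(configs), length(configs) >= 1L,
    all(vapply(configs, inherits, logical(1), "pipeline_config")),
    all(analyses %in% c("overall_loocv", "train_size", "test_size")),
    length(analyses) >= 1L
  )
  structure(
    list(
      cohort = cohort, plan = plan, configs = configs,
      analyses = analyses, out_dir = out_dir, seed = as.integer(seed),
      test_n = as.integer(test_n), pool_n = as.integer(pool_n),
      holdout_frac = holdout_frac, figures = isTRUE(figures)
    ),
    class = "run_config"
  )
}

#' Read and write run configurations as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(
    cohort = if (inherits(config$cohort, "cohort_spec")) {
      unclass(config$cohort)
    } else {
      list(path = config$cohort)
    },
    plan = unclass(config$plan),
    configs = lapply(config$configs, config_to_list),
    analyses = config$analyses,
    out_dir = config$out_dir,
    seed = config$seed,
    test_n = config$test_n,
    pool_n = config$pool_n,
    holdout_frac = config$holdout_frac,
    figures = config$figures
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  cohort <- if (!is.null(x$cohort$path)) {
    x$cohort$path
  } else {
    do.call(cohort_spec, x$cohort)
  }
  run_config(
    cohort = cohort,
    plan = do.call(sampling_plan, x$plan),
    configs = lapply(x$configs, config_from_list),
    analyses = x$analyses,
    out_dir = x$out_dir,
    seed = x$seed,
    test_n = x$test_n,
    pool_n = x$pool_n,
    holdout_frac = x$holdout_frac,
    figures = isTRUE(x$figures)
  )
}

validate_run_feasibility <- function(rc, cohort) {
  cc <- class_counts(cohort)
  m <- min(cc)
  max_n <- max(rc$plan$n_values)
  if ("overall_loocv" %in% rc$analyses && max_n > 2L * m) {
    stop("plan's largest size exceeds the balanced cohort", call. = FALSE)
  }
  if ("train_size" %in% rc$analyses &&
    rc$test_n / 2 + ceiling(max_n / 2) > m) {
    stop("cohort too small for the training-set-size analysis", call. = FALSE)
  }
  if ("test_size" %in% rc$analyses) {
    rem <- m - rc$pool_n / 2
    if (max_n > rc$pool_n || rem - round(rc$holdout_frac * rem) < 1) {
      stop("cohort too small for the test-set-size analysis", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Execute a configured run
#'
#' Validates feasibility before any compute, generates (or loads) and
#' balances the cohort, runs every requested analysis for every pipeline
#' configuration with independent per-configuration seeds, and writes to
#' the output directory:
#'
#' * `accuracies.csv` — tidy per-replicate accuracies (one row per
#'   analysis x config x size x replicate),
#' * `summary_<analysis>_<label>.csv` — per-size min/max/mean/SD and
#'   exceedance table per analysis and configuration,
#' * `provenance.json` — run configuration, seeds, package version, fit
#'   counts, and per-analysis details (test/pool splits, frozen pool
#'   correctness, holdout accuracy),
#' * `run.log` — progress log,
#' * optionally `figure_<analysis>.png` (see [run_config()]).
#'
#' @param rc A [run_config()].
#' @return The output directory path, invisibly.
#' @seealso [compare_to_oracle()] to check a finished run against the
#'   analytic oracles.
#' @export
run_study <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(rc$out_dir, "run.log")
  log_lines <- character(0)
  log_msg <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  cohort <- if (inherits(rc$cohort, "cohort_spec")) {
    log_msg("generating cohort: %d cases, %d controls, %d features",
      rc$cohort$n_cases, rc$cohort$n_controls, rc$cohort$n_features)
    generate_cohort(rc$cohort)
  } else {
    log_msg("loading cohort from %s", rc$cohort)
    read_cohort(rc$cohort)
  }
  balanced <- random_undersample(cohort, seed = derive_seed(rc$seed, 5L))
  validate_run_feasibility(rc, balanced)
  cc <- class_counts(balanced)
  log_msg("balanced cohort: %d per class", cc[["case"]])

  plan <- sampling_plan(rc$plan$n_values, rc$plan$reps_per_n,
    rc$plan$balance_mode,
    master_seed = rc$seed
  )
  grids <- list()
  details <- list()
  for (analysis in rc$analyses) {
    log_msg("running %s for %d configuration(s)", analysis, length(rc$configs))
    extra_args <- switch(analysis,
      overall_loocv = list(),
      train_size = list(test_n = rc$test_n),
      test_size = list(pool_n = rc$pool_n, holdout_frac = rc$holdout_frac)
    )
    res <- do.call(run_config_sweep, c(
      list(balanced, plan, rc$configs, analysis), extra_args
    ))[names2 <- vapply(rc$configs, function(c) c$label, character(1))]
    for (label in names2) {
      grid <- res[[label]]
      grids[[length(grids) + 1L]] <- tibble::as_tibble(grid)
      pv <- attr(grid, "provenance")
      details[[analysis]][[label]] <- pv[setdiff(names(pv), c("plan", "config", "cohort"))]
      st <- summarize_grid(grid)
      write_summary_table(
        st, file.path(rc$out_dir, sprintf("summary_%s_%s.csv", analysis, label))
      )
      log_msg("  %s: %d fits, mean accuracy at largest size %.4f",
        label, pv$n_fits %||% NA_integer_,
        st$mean[which.max(st$n)])
    }
    if (rc$figures) write_run_figure(res, analysis, rc$out_dir)
  }
  accuracies <- dplyr::bind_rows(grids)
  readr::write_csv(accuracies, file.path(rc$out_dir, "accuracies.csv"),
    progress = FALSE
  )
  provenance <- list(
    package_version = as.character(utils::packageVersion("misestimatr")),
    seed = rc$seed,
    cohort = if (inherits(rc$cohort, "cohort_spec")) unclass(rc$cohort) else rc$cohort,
    balanced_per_class = unname(cc[["case"]]),
    plan = unclass(plan),
    configs = lapply(rc$configs, config_to_list),
    analyses = rc$analyses,
    test_n = rc$test_n, pool_n = rc$pool_n, holdout_frac = rc$holdout_frac,
    details = details
  )
  jsonlite::write_json(provenance, file.path(rc$out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  writeLines(log_lines, log_path)
  invisible(rc$out_dir)
}

write_run_figure <- function(grids, analysis, out_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE) ||
    !requireNamespace("patchwork", quietly = TRUE)) {
    return(invisible(NULL))
  }
  panels <- unlist(lapply(grids, function(g) plot_accuracy_grid(g)), recursive = FALSE)
  fig <- Reduce(`+`, panels) + patchwork::plot_layout(ncol = 2)
  ggplot2::ggsave(file.path(out_dir, sprintf("figure_%s.png", analysis)),
    fig,
    width = 10, height = 4 * length(grids), dpi = 150
  )
  invisible(NULL)
}

#' Exceedance-curve and envelope panels for an accuracy grid
#'
#' Builds the two standard diagnostic panels for one analysis and
#' configuration: exceedance probability `P(accuracy >= tau)` as a function
#' of sample size (one curve per threshold), and the min/max envelope with
#' the mean accuracy.  Requires ggplot2.
#'
#' @param grid An `accuracy_grid`.
#' @param thresholds Thresholds for the exceedance panel.
#' @return List of two ggplot objects.
#' @export
plot_accuracy_grid <- function(grid, thresholds = seq(0.55, 0.9, by = 0.05)) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  st <- summarize_grid(grid, thresholds)
  label <- unique(grid$config_label)[1]
  ex <- tibble::as_tibble(st)[c("n", sprintf("p_ge_%g", thresholds))]
  ex_long <- stats::reshape(as.data.frame(ex),
    direction = "long", varying = list(2:ncol(ex)),
    v.names = "p", timevar = "tau", times = thresholds, idvar = "n"
  )
  p1 <- ggplot2::ggplot(
    ex_long,
    ggplot2::aes(x = .data$n, y = .data$p, colour = factor(.data$tau))
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "sample size N", y = "P(accuracy ≥ τ)",
      colour = "τ", title = label
    ) +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(st, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::labs(x = "sample size N", y = "accuracy", title = label) +
    ggplot2::theme_minimal()
  list(p1, p2)
}

#' Check a finished run against the analytic oracles
#'
#' Re-derives, for every analysis in a run directory that has an exact
#' analytic sampling distribution, the per-size oracle mean, SD and
#' exceedance probability, and compares them with the run's empirical
#' values via z-scores:
#'
#' * dummy-prior configurations — exact binomial tails
#'   ([binomial_exceedance()]) in every analysis;
#' * the test-set-size analysis — the two-class hypergeometric oracle
#'   ([pool_subsample_moments()], [pool_subsample_exceedance()]) fed with
#'   the frozen pool correctness recorded in the run's provenance (any
#'   configuration).
#'
#' @param run_dir Directory written by [run_study()].
#' @param tau Threshold for the exceedance comparison.
#' @param z_limit Absolute z-score above which a row is flagged.
#' @return Tibble with columns `analysis`, `config_label`, `n`,
#'   `statistic`, `empirical`, `oracle`, `z`, `flagged`; attribute `ok` is
#'   `TRUE` when no row is flagged.
#' @export
compare_to_oracle <- function(run_dir, tau = 0.7, z_limit = 4) {
  acc_path <- file.path(run_dir, "accuracies.csv")
  pv_path <- file.path(run_dir, "provenance.json")
  if (!file.exists(acc_path) || !file.exists(pv_path)) {
    stop("`run_dir` must contain accuracies.csv and provenance.json", call. = FALSE)
  }
  acc <- readr::read_csv(acc_path, show_col_types = FALSE, progress = FALSE)
  pv <- jsonlite::read_json(pv_path, simplifyVector = TRUE)
  dummy_labels <- vapply(
    seq_len(nrow(pv$configs)),
    function(i) {
      if (identical(pv$configs$classifier$type[i], "dummy_prior")) {
        pv$configs$label[i]
      } else {
        NA_character_
      }
    }, character(1)
  )
  dummy_labels <- dummy_labels[!is.na(dummy_labels)]

  rows <- list()
  add_rows <- function(sub, oracle_mean, oracle_sd_single, oracle_exc, analysis, label) {
    st <- summarize_grid(sub, thresholds = tau)
    reps <- st$n_reps
    z_mean <- (st$mean - oracle_mean) / (oracle_sd_single / sqrt(reps))
    z_sd <- (st$sd - oracle_sd_single) / (oracle_sd_single / sqrt(2 * (reps - 1)))
    se_exc <- sqrt(oracle_exc * (1 - oracle_exc) / reps)
    emp_exc <- st[[sprintf("p_ge_%g", tau)]]
    z_exc <- ifelse(se_exc > 0, (emp_exc - oracle_exc) / se_exc,
      ifelse(emp_exc == oracle_exc, 0, Inf)
    )
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      analysis = analysis, config_label = label,
      n = rep(st$n, 3L),
      statistic = rep(c("mean", "sd", paste0("p_ge_", tau)), each = nrow(st)),
      empirical = c(st$mean, st$sd, emp_exc),
      oracle = c(oracle_mean, oracle_sd_single, oracle_exc),
      z = c(z_mean, z_sd, z_exc)
    )
  }

  found <- FALSE
  for (analysis in unique(acc$analysis)) {
    for (label in unique(acc$config_label[acc$analysis == analysis])) {
      sub <- acc[acc$analysis == analysis & acc$config_label == label, ]
      if (analysis != "test_size" && label %in% dummy_labels) {
        # fresh feature-blind predictions per replicate: exact binomial
        found <- TRUE
        m <- tapply(sub$m, sub$n, function(v) v[1])[as.character(sort(unique(sub$n)))]
        add_rows(
          sub,
          oracle_mean = rep(0.5, length(m)),
          oracle_sd_single = sqrt(0.25 / m),
          oracle_exc = vapply(m, function(mm) binomial_exceedance(mm, 0.5, tau), numeric(1)),
          analysis, label
        )
      } else if (analysis == "test_size") {
        # predictions frozen once into the pool (dummy included): the
        # subsampling distribution is hypergeometric given the realized pool
        found <- TRUE
        pool_info <- pv$details[["test_size"]][[label]]$pool
        pool <- pool_correctness(
          pool_info$pool$case, pool_info$pool$control,
          pool_info$correct$case, pool_info$correct$control
        )
        sub <- sub[sub$n %% 2L == 0L, ] # oracle is defined for balanced sizes
        ns <- sort(unique(sub$n))
        mom <- vapply(ns, function(n) pool_subsample_moments(pool, n), numeric(2))
        add_rows(
          sub,
          oracle_mean = mom["mean", ],
          oracle_sd_single = mom["sd", ],
          oracle_exc = vapply(ns, function(n) pool_subsample_exceedance(pool, n, tau), numeric(1)),
          analysis, label
        )
      }
    }
  }
  if (!found) {
    stop("run contains neither a dummy-prior configuration nor a test_size analysis",
      call. = FALSE
    )
  }
  report <- dplyr::bind_rows(rows)
  report$flagged <- abs(report$z) > z_limit
  structure(report, ok = !any(report$flagged))
}
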