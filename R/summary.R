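#' Per-size distribution summary of an accuracy grid
#'
#' For each sample size `n` in the grid, computes the minimum, maximum,
#' mean and standard deviation of the replicate accuracies, and the
#' empirical exceedance probability `P(accuracy >= tau)` for every
#' threshold.  The threshold comparison is inclusive and performed on
#' integer correct counts (`round(accuracy * m) >= ceiling(tau * m)`, with
#' `m` the number of evaluated predictions behind each accuracy), so
#' accuracies exactly on a threshold always count and floating-point
#' boundary errors cannot occur.  The standard deviation uses the sample
#' (`n - 1`) convention, recorded in the `sd_convention` attribute.
#'
#' @param grid An `accuracy_grid` (or any data frame with columns `n`,
#'   `m`, `accuracy`).
#' @param thresholds Accuracy thresholds in `[0, 1]`; default
#'   `seq(0.5, 0.95, 0.05)`.
#' @return A `summary_table`: tibble with one row per `n` and columns
#'   `n`, `n_reps`, `min`, `max`, `mean`, `sd` and `p_ge_<tau>` per
#'   threshold; attributes `thresholds` and `sd_convention`.
#' @export
#' @examples
#' grid <- data.frame(n = 20, m = 20, accuracy = c(0.4, 0.7, 0.8))
#' summarize_grid(grid, thresholds = 0.7)$p_ge_0.7 # 2/3: inclusive >=
summarize_grid <- function(grid, thresholds = seq(0.5, 0.95, by = 0.05)) {
  stopifnot(
    is.data.frame(grid), nrow(grid) >= 1,
    all(c("n", "m", "accuracy") %in% names(grid)),
    is.numeric(thresholds), all(thresholds >= 0), all(thresholds <= 1)
  )
  base <- grid |>
    dplyr::group_by(.data$n) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      min = min(.data$accuracy),
      max = max(.data$accuracy),
      mean = mean(.data$accuracy),
      sd = if (dplyr::n() > 1L) stats::sd(.data$accuracy) else 0,
      .groups = "drop"
    )
  correct <- as.integer(round(grid$accuracy * grid$m))
  for (tau in thresholds) {
    hit <- correct >= min_correct_for_tau(tau, grid$m)
    ex <- tapply(hit, grid$n, mean)
    base[[sprintf("p_ge_%g", tau)]] <- as.vector(ex[as.character(base$n)])
  }
  structure(base,
    class = c("summary_table", class(base)),
    thresholds = thresholds,
    sd_convention = "sample"
  )
}

#' Write a summary table to CSV or JSON
#'
#' CSV has one row per sample size; JSON additionally records the
#' threshold grid and the SD convention.
#'
#' @param x A `summary_table` from [summarize_grid()].
#' @param path Output path; `.json` extension selects JSON, anything else
#'   CSV.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(x, path) {
  stopifnot(inherits(x, "summary_table"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(
        thresholds = attr(x, "thresholds"),
        sd_convention = attr(x, "sd_convention"),
        rows = tibble::as_tibble(x)
      ),
      path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  } else {
    readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  }
  invisible(path)
}
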