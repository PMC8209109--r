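#' Specify a synthetic case/control cohort
#'
#' A `cohort_spec` fixes everything needed to generate a reproducible
#' synthetic cohort: class sizes, feature dimension, the true (Bayes)
#' accuracy of the optimal classifier, an optional multi-site structure,
#' and a seed.
#'
#' The generative model is a pair of equal-covariance spherical Gaussian
#' classes in `n_features` dimensions whose mean difference has Mahalanobis
#' norm `calibrate_separation(target_bayes_accuracy)`, spread uniformly over
#' all features.  This is the simplest model with an exact closed-form Bayes
#' accuracy (`bayes_accuracy()`), which is what makes the calibration
#' testable.  Site effects, when enabled, are additive per-site constant
#' offsets drawn once per site.
#'
#' @param n_cases,n_controls Number of case and control subjects (each >= 1).
#'   Defaults mirror a pooled two-cohort clinical sample with 1306 cases and
#'   934 controls, i.e. a moderately imbalanced case-heavy cohort.
#' @param n_features Feature dimension (>= 1).  Default 500: desk-scale, but
#'   still features >> subjects for the small subsample sizes the experiments
#'   draw.
#' @param target_bayes_accuracy True accuracy of the Bayes-optimal classifier,
#'   in `[0.5, 1)`.  Exactly 1 is rejected (it would require infinite class
#'   separation).  Default 0.61, a weakly separable problem.
#' @param n_sites Number of acquisition sites (>= 1); subjects are assigned
#'   to sites cyclically.
#' @param site_shift_scale Standard deviation of the per-feature additive
#'   site offset.  Default 0 (no site effect); the knob exists for
#'   sensitivity checks only.
#' @param seed Integer seed; the whole cohort is a pure function of the spec.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [calibrate_separation()]
#' @export
#' @examples
#' spec <- cohort_spec(n_cases = 60, n_controls = 40, n_features = 20, seed = 1)
#' coh <- generate_cohort(spec)
#' table(coh$labels)
cohort_spec <- function(n_cases = 1306L, n_controls = 934L, n_features = 500L,
                        target_bayes_accuracy = 0.61, n_sites = 3L,
                        site_shift_scale = 0, seed = 1L) {
  stopifnot(
    length(n_cases) == 1L, n_cases >= 1,
    length(n_controls) == 1L, n_controls >= 1,
    length(n_features) == 1L, n_features >= 1,
    length(n_sites) == 1L, n_sites >= 1,
    length(site_shift_scale) == 1L, site_shift_scale >= 0,
    length(seed) == 1L, is.finite(seed)
  )
  if (!is.numeric(target_bayes_accuracy) ||
      target_bayes_accuracy < 0.5 || target_bayes_accuracy >= 1) {
    stop("`target_bayes_accuracy` must lie in [0.5, 1)", call. = FALSE)
  }
  structure(
    list(
      n_cases = as.integer(n_cases),
      n_controls = as.integer(n_controls),
      n_features = as.integer(n_features),
      target_bayes_accuracy = as.numeric(target_bayes_accuracy),
      n_sites = as.integer(n_sites),
      site_shift_scale = as.numeric(site_shift_scale),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d cases / %d controls, %d features, Bayes acc %.3f, %d site(s), seed %d\n",
    x$n_cases, x$n_controls, x$n_features, x$target_bayes_accuracy,
    x$n_sites, x$seed
  ))
  invisible(x)
}

#' Class separation needed for a target Bayes accuracy
#'
#' For two equal-covariance spherical Gaussian classes whose mean difference
#' has Mahalanobis norm `d`, the Bayes-optimal classifier (equal priors) has
#' accuracy `pnorm(d / 2)`.  This function inverts that relation:
#' `calibrate_separation(a)` returns `d = 2 * qnorm(a)`, so that
#' `bayes_accuracy(calibrate_separation(a)) == a` to machine precision.
#'
#' @param target_bayes_accuracy Desired Bayes accuracy, in `[0.5, 1)`.
#' @return The Mahalanobis distance between class means (nonnegative scalar).
#' @seealso [bayes_accuracy()] for the forward direction.
#' @export
#' @examples
#' calibrate_separation(0.5)   # 0: no separation at chance level
#' calibrate_separation(0.61)  # ~0.559, a weakly separable problem
calibrate_separation <- function(target_bayes_accuracy) {
  if (!is.numeric(target_bayes_accuracy) ||
      any(target_bayes_accuracy < 0.5) || any(target_bayes_accuracy >= 1)) {
    stop("`target_bayes_accuracy` must lie in [0.5, 1)", call. = FALSE)
  }
  2 * stats::qnorm(target_bayes_accuracy)
}

new_cohort <- function(features, labels, sites, subject_ids) {
  stopifnot(
    is.matrix(features),
    nrow(features) == length(labels),
    nrow(features) == length(sites),
    nrow(features) == length(subject_ids)
  )
  labels <- factor(as.character(labels), levels = c("case", "control"))
  if (anyNA(labels)) stop("labels must be 'case' or 'control'", call. = FALSE)
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique", call. = FALSE)
  if (!all(is.finite(features))) stop("features must be finite", call. = FALSE)
  structure(
    list(
      features = features,
      labels = labels,
      sites = as.integer(sites),
      subject_ids = as.character(subject_ids)
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf(
    "<cohort> %d subjects (%d cases, %d controls), %d features, %d site(s)\n",
    nrow(x$features), tab[["case"]], tab[["control"]],
    ncol(x$features), length(unique(x$sites))
  ))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param x A `cohort`.
#' @return Integer subject count.
#' @export
n_subjects <- function(x) {
  stopifnot(inherits(x, "cohort"))
  nrow(x$features)
}

class_counts <- function(cohort) {
  tab <- table(cohort$labels)
  c(case = unname(tab[["case"]]), control = unname(tab[["control"]]))
}

is_balanced <- function(cohort) {
  cc <- class_counts(cohort)
  cc[["case"]] == cc[["control"]]
}

#' Generate a synthetic case/control cohort
#'
#' Draws a cohort from the generative model described in [cohort_spec()]:
#' standard-normal features with a per-feature mean shift of
#' `d / sqrt(n_features)` between classes (`d` from
#' [calibrate_separation()]), plus optional per-site additive offsets.
#' Cases occupy the first `n_cases` rows.  The result is a pure function of
#' the spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort`: list with `features` (subjects x features matrix),
#'   `labels` (factor, levels `case`/`control`), `sites` (integer), and
#'   `subject_ids` (character, unique).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(30, 20, n_features = 10, seed = 7))
#' dim(coh$features)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cases + spec$n_controls
  p <- spec$n_features
  d <- calibrate_separation(spec$target_bayes_accuracy)
  shift <- d / sqrt(p) # per-feature shift; total Mahalanobis norm d
  withr::with_seed(spec$seed, {
    x <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
    labels <- rep(c("case", "control"), times = c(spec$n_cases, spec$n_controls))
    x[labels == "case", ] <- x[labels == "case", ] + shift / 2
    x[labels == "control", ] <- x[labels == "control", ] - shift / 2
    sites <- rep_len(seq_len(spec$n_sites), n)
    # site offsets drawn after the features so that site_shift_scale = 0
    # leaves the class-conditional distributions untouched for any n_sites
    for (s in seq_len(spec$n_sites)) {
      offset <- stats::rnorm(p, 0, spec$site_shift_scale)
      rows <- which(sites == s)
      x[rows, ] <- x[rows, ] + matrix(offset, length(rows), p, byrow = TRUE)
    }
    colnames(x) <- paste0("f", seq_len(p) - 1L)
    new_cohort(x, labels, sites, sprintf("S%05d", seq_len(n)))
  })
}

#' Oracle class-mean direction of a synthetic cohort
#'
#' The true (population) difference between class means for a cohort drawn
#' from `spec`, used to build the Bayes-optimal linear rule in calibration
#' checks.  Independent of any fitted model.
#'
#' @param spec A [cohort_spec()].
#' @return Numeric vector of length `n_features` (case mean minus control mean).
#' @keywords internal
#' @export
oracle_mean_shift <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  d <- calibrate_separation(spec$target_bayes_accuracy)
  rep(d / sqrt(spec$n_features), spec$n_features)
}

#' Subset a cohort by subject index
#'
#' @param cohort A `cohort`.
#' @param idx Integer subject indices (may be negative for exclusion).
#' @return The subsetted `cohort`.
#' @export
subset_cohort <- function(cohort, idx) {
  stopifnot(inherits(cohort, "cohort"))
  new_cohort(
    cohort$features[idx, , drop = FALSE],
    cohort$labels[idx],
    cohort$sites[idx],
    cohort$subject_ids[idx]
  )
}

#' Balance a cohort by random under-sampling
#'
#' Discards randomly chosen majority-class subjects until both classes have
#' `min(class counts)` subjects, removing prevalence as a confound before
#' any accuracy analysis.  The minority class is untouched; majority
#' subjects are chosen uniformly without replacement.  An already balanced
#' cohort is returned unchanged.
#'
#' @param cohort A `cohort` with at least one subject in each class.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A balanced `cohort`; retained subjects keep their original order.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(30, 20, n_features = 5, seed = 2))
#' table(random_undersample(coh, seed = 1)$labels)
random_undersample <- function(cohort, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  cc <- class_counts(cohort)
  if (any(cc < 1)) stop("both classes must be non-empty", call. = FALSE)
  m <- min(cc)
  if (cc[["case"]] == cc[["control"]]) return(cohort)
  majority <- if (cc[["case"]] > cc[["control"]]) "case" else "control"
  maj_idx <- which(cohort$labels == majority)
  keep_maj <- withr::with_seed(seed, sample(maj_idx, m))
  keep <- sort(c(which(cohort$labels != majority), keep_maj))
  subset_cohort(cohort, keep)
}

#' Read and write cohorts as delimited text or RDS
#'
#' The text form is a CSV with one header row and columns `subject_id`,
#' `label`, `site`, `f0` ... `f{p-1}`; doubles are written in shortest
#' round-trip representation so a write/read cycle reproduces the cohort
#' exactly.  The binary form is a plain RDS serialization of the `cohort`
#' object.  The format is chosen from the file extension (`.rds` for binary,
#' anything else is treated as CSV).
#'
#' @param cohort A `cohort`.
#' @param path File path; extension selects the format.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a `cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(cohort, path)
    return(invisible(path))
  }
  df <- data.frame(
    subject_id = cohort$subject_ids,
    label = as.character(cohort$labels),
    site = cohort$sites,
    stringsAsFactors = FALSE
  )
  # 17 significant digits: exact round trip for IEEE doubles
  feat <- as.data.frame(matrix(sprintf("%.17g", cohort$features),
    nrow = nrow(cohort$features)
  ), stringsAsFactors = FALSE)
  names(feat) <- paste0("f", seq_len(ncol(cohort$features)) - 1L)
  readr::write_csv(cbind(df, feat), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    coh <- readRDS(path)
    stopifnot(inherits(coh, "cohort"))
    return(coh)
  }
  df <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("subject_id", "label", "site")
  if (!all(required %in% names(df))) {
    stop("cohort file must have columns subject_id, label, site, f0...", call. = FALSE)
  }
  feat_cols <- setdiff(names(df), required)
  # base-R numeric conversion is correctly rounded, so %.17g round-trips exactly
  x <- matrix(as.numeric(as.matrix(df[feat_cols])), nrow = nrow(df))
  colnames(x) <- feat_cols
  new_cohort(x, df$label, df$site, df$subject_id)
}
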