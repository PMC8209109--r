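#' Classification pipeline configuration
#'
#' A `pipeline_config` fully specifies one leakage-free classification
#' pipeline: an optional per-feature standardization step, an optional
#' dimensionality reducer, and a classifier.  Every stage is fit on training
#' rows only; a zero-variance filter always runs first (constant features
#' carry no information and break standardization).
#'
#' @param classifier A classifier spec from [linear_svm()], [rbf_svm()],
#'   [random_forest()], [dummy_prior()] or [majority_vote()].
#' @param reducer A reducer spec from [reducer_none()], [reducer_pca()] or
#'   [reducer_f_select()].
#' @param standardize Scale features to zero mean / unit variance, with the
#'   statistics estimated on training rows only.
#' @param label Short text identifier; autogenerated from the parts when
#'   `NULL`.
#' @return An object of class `pipeline_config`.
#' @export
#' @examples
#' default_pipeline()
#' pipeline_config(rbf_svm(C = 1), reducer_pca(10))
pipeline_config <- function(classifier = linear_svm(),
                            reducer = reducer_none(),
                            standardize = TRUE,
                            label = NULL) {
  stopifnot(
    inherits(classifier, "classifier_spec"),
    inherits(reducer, "reducer_spec"),
    is.logical(standardize), length(standardize) == 1L
  )
  if (is.null(label)) {
    label <- paste0(classifier$label, if (reducer$type != "none") paste0("__", reducer$label))
  }
  structure(
    list(
      classifier = classifier,
      reducer = reducer,
      standardize = standardize,
      label = label
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "<pipeline_config> %s | standardize=%s, reducer=%s, classifier=%s\n",
    x$label, x$standardize, x$reducer$label, x$classifier$label
  ))
  invisible(x)
}

#' The study's default pipeline
#'
#' Zero-variance filter, per-feature standardization and a linear SVM with
#' conventional default hyperparameters (`C = 1`), all fit inside each
#' training fold.
#'
#' @return A `pipeline_config`.
#' @export
default_pipeline <- function() pipeline_config(linear_svm())

# ---- classifier and reducer specs ------------------------------------------

classifier_spec <- function(type, label, ...) {
  structure(list(type = type, label = label, ...), class = "classifier_spec")
}

#' Classifier specifications
#'
#' @description
#' Building blocks for [pipeline_config()]:
#'
#' * `linear_svm(C)` — soft-margin linear support-vector machine.
#' * `rbf_svm(C, gamma)` — radial-basis-function SVM; `gamma = NULL` uses the
#'   scale-like default `1 / (n_features * var(X))` computed on the training
#'   matrix after standardization.
#' * `random_forest(n_trees, seed)` — random forest ensemble.
#' * `dummy_prior(seed)` — chance-level baseline: ignores all features and
#'   predicts each label stochastically from the training class prevalence.
#'   On a balanced training set its true accuracy is exactly 50% no matter
#'   the test set, so its estimated-accuracy distribution is exactly
#'   `Binomial(m, 1/2) / m` over `m` test predictions.  When `seed` is
#'   `NULL` a prediction seed is drawn from the ambient RNG stream at fit
#'   time, making refits independent while the fitted model itself predicts
#'   deterministically.  Under [loocv_accuracy()] the prior is taken from
#'   the full sample under analysis (see there).
#' * `majority_vote()` — degenerate baseline predicting the majority class of
#'   the training set (ties go to `case`).  Under leave-one-out
#'   cross-validation on a balanced sample it scores exactly 0, the classic
#'   LOOCV pathology; shipped as a negative control to distinguish it from
#'   the stochastic prior dummy.
#'
#' @param C Soft-margin cost, > 0.
#' @param gamma RBF kernel width, > 0, or `NULL` for the scale-like default.
#' @param n_trees Number of trees, >= 1.
#' @param seed Optional integer seed pinning the stochastic parts of the
#'   classifier (tree growing, dummy label draws).
#' @return A `classifier_spec`.
#' @name classifiers
NULL

#' @rdname classifiers
#' @export
linear_svm <- function(C = 1) {
  stopifnot(is.numeric(C), length(C) == 1L, C > 0)
  classifier_spec("linear_svm", sprintf("linear_svm_C%g", C), C = C)
}

#' @rdname classifiers
#' @export
rbf_svm <- function(C = 1, gamma = NULL) {
  stopifnot(is.numeric(C), length(C) == 1L, C > 0)
  if (!is.null(gamma)) stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma > 0)
  classifier_spec(
    "rbf_svm",
    sprintf("rbf_svm_C%g%s", C, if (is.null(gamma)) "" else sprintf("_g%g", gamma)),
    C = C, gamma = gamma
  )
}

#' @rdname classifiers
#' @export
random_forest <- function(n_trees = 500L, seed = NULL) {
  stopifnot(is.numeric(n_trees), length(n_trees) == 1L, n_trees >= 1)
  classifier_spec("random_forest", sprintf("random_forest_t%d", as.integer(n_trees)),
    n_trees = as.integer(n_trees), seed = seed
  )
}

#' @rdname classifiers
#' @export
dummy_prior <- function(seed = NULL) {
  classifier_spec("dummy_prior", "dummy_prior", seed = seed)
}

#' @rdname classifiers
#' @export
majority_vote <- function() {
  classifier_spec("majority_vote", "majority_vote")
}

reducer_spec <- function(type, label, ...) {
  structure(list(type = type, label = label, ...), class = "reducer_spec")
}

#' Dimensionality reducer specifications
#'
#' @description
#' * `reducer_none()` — pass features through unchanged.
#' * `reducer_pca(k)` — project onto the first `k` principal components of
#'   the training matrix; `k` is capped at `min(training rows - 1, columns)`
#'   at fit time.
#' * `reducer_f_select(k)` — keep the `k` features with the largest one-way
#'   ANOVA F statistic between the two classes, ties broken by lower column
#'   index; `k` is capped at the number of available columns.
#'
#' @param k Number of components / features to keep, >= 1.
#' @return A `reducer_spec`.
#' @name reducers
NULL

#' @rdname reducers
#' @export
reducer_none <- function() reducer_spec("none", "none")

#' @rdname reducers
#' @export
reducer_pca <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  reducer_spec("pca", sprintf("pca_k%d", as.integer(k)), k = as.integer(k))
}

#' @rdname reducers
#' @export
reducer_f_select <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  reducer_spec("f_select", sprintf("f_select_k%d", as.integer(k)), k = as.integer(k))
}

# ---- zero-variance filter ---------------------------------------------------

#' Drop features with zero variance
#'
#' Removes exactly the columns whose sample variance on the given rows is
#' zero (constant features: the "background" of an image-derived feature
#' matrix).  Run on training rows inside every fold by [fit_pipeline()].
#'
#' @param features Numeric matrix with at least one row.
#' @return List with `features` (reduced matrix) and `mask` (logical vector
#'   over the input columns, `TRUE` = kept).
#' @export
#' @examples
#' remove_zero_variance(matrix(c(1, 2, 5, 5, 5, 7), nrow = 2))
remove_zero_variance <- function(features) {
  stopifnot(is.matrix(features), nrow(features) >= 1)
  cm <- colMeans(features)
  ss <- colSums(sweep(features, 2L, cm)^2)
  mask <- ss > 0
  if (!any(mask)) stop("all features are constant; no usable features", call. = FALSE)
  list(features = features[, mask, drop = FALSE], mask = mask)
}

# ---- fitting ----------------------------------------------------------------

f_statistic <- function(x, y) {
  # one-way ANOVA F per column for a two-level factor, vectorized
  g1 <- y == levels(y)[1L]
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  m <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  ssw <- colSums(sweep(x[g1, , drop = FALSE], 2L, m1)^2) +
    colSums(sweep(x[!g1, , drop = FALSE], 2L, m2)^2)
  ssb / (ssw / (n - 2))
}

#' Fit a classification pipeline on training data
#'
#' Fits every stage — zero-variance filter, scaler, reducer, classifier —
#' on the supplied training rows only, so that no statistic of any later
#' test subject can leak into the model.
#'
#' @param config A [pipeline_config()].
#' @param features Training matrix (subjects x features).
#' @param labels Training labels: factor/character with levels
#'   `case`/`control`.
#' @return A `trained_model`; predictions depend only on its fitted state.
#' @export
#' @examples
#' x <- rbind(c(-1, 0), c(1, 0))
#' m <- fit_pipeline(default_pipeline(), x, c("case", "control"))
#' predict(m, x)
fit_pipeline <- function(config, features, labels) {
  stopifnot(inherits(config, "pipeline_config"), is.matrix(features))
  labels <- factor(as.character(labels), levels = c("case", "control"))
  if (anyNA(labels) || length(labels) != nrow(features)) {
    stop("labels must be case/control and match the feature rows", call. = FALSE)
  }
  clf <- config$classifier
  if (clf$type %in% c("linear_svm", "rbf_svm", "random_forest", "majority_vote")) {
    if (nlevels(droplevels(labels)) < 2L) {
      stop("training set contains a single class", call. = FALSE)
    }
  } else if (length(labels) < 1L) {
    stop("empty training set", call. = FALSE)
  }

  zv <- remove_zero_variance(features)
  x <- zv$features

  center <- scale_sd <- NULL
  if (config$standardize) {
    center <- colMeans(x)
    scale_sd <- sqrt(colSums(sweep(x, 2L, center)^2) / max(1L, nrow(x) - 1L))
    scale_sd[scale_sd == 0] <- 1 # single training row: center only
    x <- sweep(sweep(x, 2L, center), 2L, scale_sd, "/")
  }

  red <- config$reducer
  reducer_fit <- NULL
  if (red$type == "pca") {
    k <- min(red$k, nrow(x) - 1L, ncol(x))
    if (k < 1L) stop("PCA needs at least 2 training rows", call. = FALSE)
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    reducer_fit <- list(type = "pca", center = pc$center,
                        rotation = pc$rotation[, seq_len(k), drop = FALSE],
                        k = k, k_requested = red$k)
    x <- sweep(x, 2L, pc$center) %*% reducer_fit$rotation
  } else if (red$type == "f_select") {
    k <- min(red$k, ncol(x))
    f <- f_statistic(x, labels)
    f[!is.finite(f)] <- Inf # zero within-class variance: perfectly informative
    keep <- sort(order(-f, seq_along(f))[seq_len(k)])
    reducer_fit <- list(type = "f_select", keep = keep, k = k, k_requested = red$k)
    x <- x[, keep, drop = FALSE]
  }

  fit <- switch(clf$type,
    linear_svm = e1071::svm(x, labels, kernel = "linear", cost = clf$C, scale = FALSE),
    rbf_svm = {
      gamma <- clf$gamma
      if (is.null(gamma)) {
        v <- stats::var(as.vector(x))
        gamma <- if (is.finite(v) && v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
      }
      e1071::svm(x, labels, kernel = "radial", cost = clf$C, gamma = gamma, scale = FALSE)
    },
    random_forest = {
      fit_one <- function() randomForest::randomForest(x, labels, ntree = clf$n_trees)
      if (is.null(clf$seed)) fit_one() else withr::with_seed(clf$seed, fit_one())
    },
    dummy_prior = {
      prior <- as.vector(table(labels)) / length(labels)
      names(prior) <- levels(labels)
      pred_seed <- if (is.null(clf$seed)) {
        sample.int(.Machine$integer.max - 1L, 1L)
      } else {
        as.integer(clf$seed)
      }
      list(prior = prior, pred_seed = pred_seed)
    },
    majority_vote = {
      tab <- table(labels)
      list(majority = names(tab)[which.max(tab)]) # tie -> first level ("case")
    },
    stop("unknown classifier type: ", clf$type, call. = FALSE)
  )

  structure(
    list(
      config = config,
      feature_mask = zv$mask,
      center = center,
      scale_sd = scale_sd,
      reducer_fit = reducer_fit,
      fit = fit,
      levels = c("case", "control"),
      n_train = nrow(features),
      p_in = ncol(features)
    ),
    class = "trained_model"
  )
}

#' Predict class labels with a trained pipeline
#'
#' Applies the stored zero-variance mask, scaler, reducer and classifier.
#' The dummy-prior classifier draws each prediction independently from its
#' fitted prevalence using the prediction seed frozen at fit time, so
#' repeated calls on the same model return identical labels.
#'
#' @param object A `trained_model` from [fit_pipeline()].
#' @param newdata Matrix with the same column count as the training matrix
#'   (before zero-variance masking).
#' @param ... Unused.
#' @return Factor of predicted labels (levels `case`/`control`).
#' @export
predict.trained_model <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != object$p_in) {
    stop(sprintf(
      "newdata has %d columns; model was trained on %d",
      ncol(newdata), object$p_in
    ), call. = FALSE)
  }
  clf <- object$config$classifier
  if (clf$type == "dummy_prior") {
    m <- nrow(newdata)
    p_case <- object$fit$prior[["case"]]
    draws <- withr::with_seed(object$fit$pred_seed, stats::runif(m) < p_case)
    return(factor(ifelse(draws, "case", "control"), levels = object$levels))
  }
  if (clf$type == "majority_vote") {
    return(factor(rep(object$fit$majority, nrow(newdata)), levels = object$levels))
  }
  x <- newdata[, object$feature_mask, drop = FALSE]
  if (object$config$standardize) {
    x <- sweep(sweep(x, 2L, object$center), 2L, object$scale_sd, "/")
  }
  rf <- object$reducer_fit
  if (!is.null(rf)) {
    if (rf$type == "pca") {
      x <- sweep(x, 2L, rf$center) %*% rf$rotation
    } else {
      x <- x[, rf$keep, drop = FALSE]
    }
  }
  pred <- switch(clf$type,
    linear_svm = ,
    rbf_svm = stats::predict(object$fit, x),
    random_forest = stats::predict(object$fit, x),
    stop("unknown classifier type: ", clf$type, call. = FALSE)
  )
  factor(as.character(pred), levels = object$levels)
}

#' Accuracy of a trained model on labelled data
#'
#' @param model A `trained_model`.
#' @param features Matrix of subjects to classify.
#' @param labels True labels.
#' @return Fraction of correct predictions, a multiple of `1/nrow(features)`.
#' @export
evaluate_accuracy <- function(model, features, labels) {
  stopifnot(nrow(features) >= 1)
  labels <- factor(as.character(labels), levels = c("case", "control"))
  mean(predict(model, features) == labels)
}

#' Leave-one-out cross-validation accuracy
#'
#' For each subject, fits the full pipeline — including the zero-variance
#' filter, scaler and reducer — on the other `N - 1` subjects and predicts
#' the held-out one; returns the fraction of held-out subjects predicted
#' correctly (a multiple of `1/N`).
#'
#' `scaler_scope = "global"` is an intentionally leaky variant that fits the
#' standardization statistics on all `N` subjects before cross-validating.
#' It exists only to demonstrate the effect of that leak; the default is the
#' leakage-free fold-internal fit.
#'
#' The feature-blind `dummy_prior` baseline is not refit inside folds: its
#' prior is the prevalence of the analysed sample (exactly 1/2 when
#' balanced), each subject's prediction an independent draw from it, so its
#' LOOCV accuracy follows the exact `Binomial(N, 1/2) / N` reference
#' distribution.  A fold-refit prior would be `(N/2 - 1)/(N - 1)` for the
#' held-out class — systematically below chance, a mild relative of the
#' majority-vote pathology.
#'
#' @param config A [pipeline_config()].
#' @param cohort A `cohort` with at least 2 subjects; SVM/forest classifiers
#'   additionally need both classes in every training fold (guaranteed for
#'   balanced cohorts of N >= 4).
#' @param scaler_scope `"fold"` (leakage-free, default) or `"global"`.
#' @return LOOCV accuracy in `[0, 1]`.
#' @export
loocv_accuracy <- function(config, cohort, scaler_scope = c("fold", "global")) {
  stopifnot(inherits(config, "pipeline_config"), inherits(cohort, "cohort"))
  scaler_scope <- match.arg(scaler_scope)
  n <- n_subjects(cohort)
  if (n < 2L) stop("LOOCV needs at least 2 subjects", call. = FALSE)
  x <- cohort$features
  y <- cohort$labels
  if (config$classifier$type == "dummy_prior") {
    # The chance-level baseline is defined by the prevalence of the sample
    # under analysis: on balanced data its prior — and hence its expected
    # accuracy — is exactly 50%, and every subject's prediction is an
    # independent draw from that prior.  (Refitting the prior inside each
    # fold would instead use the N-1 training subjects, whose prevalence is
    # (N/2 - 1)/(N - 1) for the held-out subject's class: a systematic
    # pessimistic shift of 1/(2(N-1)) — a mild relative of the
    # majority-vote pathology — which would break the exact Binomial(N, 1/2)
    # reference distribution the baseline exists to provide.)
    model <- fit_pipeline(config, x, y)
    return(mean(predict(model, x) == y))
  }
  if (scaler_scope == "global" && config$standardize) {
    zv <- remove_zero_variance(x)
    x <- scale(zv$features) # leaky: test subject informs its own scaling
    config <- pipeline_config(config$classifier, config$reducer,
      standardize = FALSE, label = config$label
    )
  }
  correct <- logical(n)
  for (i in seq_len(n)) {
    model <- fit_pipeline(config, x[-i, , drop = FALSE], y[-i])
    correct[i] <- predict(model, x[i, , drop = FALSE]) == y[i]
  }
  mean(correct)
}

# ---- configuration grids ----------------------------------------------------

#' Enumerate pipeline configurations from a grid specification
#'
#' Expands the Cartesian product of classifier settings and reducer settings
#' into a deduplicated, deterministically ordered list of
#' [pipeline_config()]s with unique labels.  A grid specification is a list
#' with elements `classifiers` and `reducers`, each a list of entries of the
#' form `list(type = ..., <hyperparameter> = <vector of values>)`; vector
#' hyperparameters are expanded.  Optional element `standardize`
#' (default `TRUE`) applies to every configuration.
#'
#' @param grid A grid specification list (see Details), e.g. the result of
#'   [yaml::read_yaml()] on a grid file.
#' @return List of `pipeline_config`s, ordered classifier-major in the order
#'   given, with duplicates removed.
#' @seealso [default_config_grid()] for the packaged 48-configuration grid.
#' @export
#' @examples
#' grid <- list(
#'   classifiers = list(list(type = "linear_svm", C = c(0.1, 1))),
#'   reducers = list(list(type = "none"), list(type = "pca", k = 10))
#' )
#' length(enumerate_configs(grid))
enumerate_configs <- function(grid) {
  stopifnot(is.list(grid))
  cls <- grid$classifiers
  red <- grid$reducers
  if (is.null(cls) || length(cls) == 0L || is.null(red) || length(red) == 0L) {
    stop("grid must list at least one classifier and one reducer", call. = FALSE)
  }
  standardize <- if (is.null(grid$standardize)) TRUE else isTRUE(grid$standardize)

  expand_classifier <- function(e) {
    switch(e$type,
      linear_svm = lapply(as.numeric(e$C %||% 1), linear_svm),
      rbf_svm = lapply(as.numeric(e$C %||% 1), function(C) rbf_svm(C = C, gamma = e$gamma)),
      random_forest = lapply(as.integer(e$n_trees %||% 500L), random_forest),
      dummy_prior = list(dummy_prior()),
      majority_vote = list(majority_vote()),
      stop("unknown classifier type in grid: ", e$type, call. = FALSE)
    )
  }
  expand_reducer <- function(e) {
    switch(e$type,
      none = list(reducer_none()),
      pca = lapply(as.integer(e$k), reducer_pca),
      f_select = lapply(as.integer(e$k), reducer_f_select),
      stop("unknown reducer type in grid: ", e$type, call. = FALSE)
    )
  }
  classifiers <- unlist(lapply(cls, expand_classifier), recursive = FALSE)
  reducers <- unlist(lapply(red, expand_reducer), recursive = FALSE)

  configs <- list()
  for (cf in classifiers) {
    for (rd in reducers) {
      cfg <- pipeline_config(cf, rd, standardize = standardize)
      configs[[cfg$label]] <- cfg # dedupe on label, keep first occurrence order
    }
  }
  unname(configs[unique(names(configs))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The packaged 48-configuration grid
#'
#' A reconstruction of a broad pipeline sweep spanning linear and RBF SVMs
#' and random forests, with no reduction, PCA, and F-test feature selection:
#' 6 classifier settings (each family at two hyperparameter values) x 8
#' reducer settings = 48 configurations.  PCA component counts stop at 100
#' because the reducer is capped at training rows minus one and the sweep is
#' aimed at training sets of at most a few hundred subjects; univariate
#' F-selection has no such cap, so it also includes `k = 500`.  The grid is
#' shipped as `inst/extdata/default_grid.yaml`.
#'
#' @return List of 48 `pipeline_config`s.
#' @export
default_config_grid <- function() {
  path <- system.file("extdata", "default_grid.yaml", package = "misestimatr",
    mustWork = TRUE
  )
  enumerate_configs(yaml::read_yaml(path))
}

#' Serialize pipeline configurations to and from YAML-style lists
#'
#' @param config A `pipeline_config`.
#' @return `config_to_list()` returns a plain nested list suitable for
#'   [yaml::write_yaml()]; `config_from_list()` rebuilds the
#'   `pipeline_config`.
#' @export
config_to_list <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  clf <- config$classifier
  red <- config$reducer
  list(
    label = config$label,
    standardize = config$standardize,
    classifier = clf[setdiff(names(clf), "label")],
    reducer = red[setdiff(names(red), "label")]
  )
}

#' @rdname config_to_list
#' @param x A list as produced by `config_to_list()`.
#' @export
config_from_list <- function(x) {
  clf <- switch(x$classifier$type,
    linear_svm = linear_svm(C = x$classifier$C),
    rbf_svm = rbf_svm(C = x$classifier$C, gamma = x$classifier$gamma),
    random_forest = random_forest(n_trees = x$classifier$n_trees, seed = x$classifier$seed),
    dummy_prior = dummy_prior(seed = x$classifier$seed),
    majority_vote = majority_vote(),
    stop("unknown classifier type: ", x$classifier$type, call. = FALSE)
  )
  red <- switch(x$reducer$type,
    none = reducer_none(),
    pca = reducer_pca(x$reducer$k),
    f_select = reducer_f_select(x$reducer$k),
    stop("unknown reducer type: ", x$reducer$type, call. = FALSE)
  )
  pipeline_config(clf, red, standardize = isTRUE(x$standardize), label = x$label)
}
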