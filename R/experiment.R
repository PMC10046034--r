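#' Classification accuracy
#'
#' Percentage of correctly classified samples:
#' `100 * (true classifications / total test samples)`.
#'
#' @param predictions,truth equal-length label vectors (non-empty).
#' @return Accuracy in percent.
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) == 0L || length(predictions) != length(truth))
    stop("predictions and truth must be equal-length and non-empty",
         call. = FALSE)
  100 * mean(as.character(predictions) == as.character(truth))
}

#' Validation scheme
#'
#' Hold-out (a test fraction), k-fold (pooled accuracy over rotating test
#' folds) or leave-one-out cross-validation.
#'
#' @param kind `"holdout"`, `"kfold"` or `"leave_one_out"`.
#' @param holdout_fraction test fraction in (0, 1) for hold-out.
#' @param k number of folds (>= 2) for k-fold.
#' @param seed RNG seed for the split.
#' @return List of class `validation_scheme`.
#' @export
validation_scheme <- function(kind = c("holdout", "kfold", "leave_one_out"),
                              holdout_fraction = 0.2, k = 10L, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "holdout" && (holdout_fraction <= 0 || holdout_fraction >= 1))
    stop("holdout_fraction must be in (0, 1)", call. = FALSE)
  if (kind == "kfold" && k < 2L) stop("k must be >= 2", call. = FALSE)
  structure(list(kind = kind, holdout_fraction = holdout_fraction,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "validation_scheme")
}

scheme_label <- function(val) {
  switch(val$kind,
         holdout = sprintf("%.1f%% holdout", 100 * val$holdout_fraction),
         kfold = sprintf("%d fold", val$k),
         leave_one_out = "leave-one-out")
}

# Build the list of (train, test) index splits for a scheme. Splits whose
# training portion holds a single class are re-drawn with a shifted seed
# (logged via the `reseeds` attribute).
make_splits <- function(y, val, seed) {
  n <- length(y)
  reseeds <- 0L
  if (val$kind == "leave_one_out") {
    splits <- lapply(seq_len(n), function(i)
      list(train = setdiff(seq_len(n), i), test = i))
    return(structure(splits, reseeds = 0L))
  }
  for (try in 0:19) {
    s <- seed + try
    splits <- local_seed(s, {
      if (val$kind == "holdout") {
        n_test <- max(1L, round(val$holdout_fraction * n))
        test <- sample.int(n, n_test)
        list(list(train = setdiff(seq_len(n), test), test = test))
      } else {
        k <- min(val$k, n)
        fold <- sample(rep_len(seq_len(k), n))
        lapply(seq_len(k), function(f)
          list(train = which(fold != f), test = which(fold == f)))
      }
    })
    ok <- all(vapply(splits,
                     function(sp) length(unique(y[sp$train])) == 2L &&
                                  length(sp$test) > 0L, logical(1)))
    if (ok) return(structure(splits, reseeds = reseeds))
    reseeds <- reseeds + 1L
  }
  stop("could not build splits with both classes in every training fold",
       call. = FALSE)
}

#' Train and evaluate one classifier under one validation scheme
#'
#' Fits the classifier on each training portion only and pools accuracy over
#' the held-out portions (for leave-one-out this equals the mean of the n
#' single-sample evaluations). Columns with zero variance in a training
#' portion are dropped from that fold. An optional `balance_fn` is applied
#' to the training portion of every fold — never to test data — so
#' oversampling cannot leak synthetic copies of test subjects into training.
#'
#' @param features numeric feature matrix or data frame.
#' @param labels factor (2 classes present overall).
#' @param clf a [classifier_spec()].
#' @param val a [validation_scheme()].
#' @param balance_fn optional `function(X, y)` returning
#'   `list(X = ..., y = ...)` applied to each training portion.
#' @param seed RNG seed governing splits and stochastic fits.
#' @return List of class `train_eval_result`: pooled `accuracy` (percent),
#'   per-fold tibble `folds`, the spec, scheme, `seed` and re-seed count.
#' @export
train_eval <- function(features, labels, clf, val, balance_fn = NULL,
                       seed = 1L) {
  X <- as.matrix(features)
  y <- droplevels(factor(labels))
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (nrow(X) != length(y)) stop("features/labels length mismatch", call. = FALSE)
  splits <- make_splits(y, val, seed)
  folds <- list()
  for (f in seq_along(splits)) {
    sp <- splits[[f]]
    Xtr <- X[sp$train, , drop = FALSE]
    ytr <- y[sp$train]
    Xte <- X[sp$test, , drop = FALSE]
    if (!is.null(balance_fn)) {
      bal <- balance_fn(Xtr, ytr)
      Xtr <- bal$X; ytr <- bal$y
    }
    keep <- apply(Xtr, 2, function(col) sd(col) > 0)
    if (!any(keep)) stop("all features constant in a training fold", call. = FALSE)
    model <- fit_classifier(clf, Xtr[, keep, drop = FALSE], ytr,
                            seed = seed + f)
    pred <- predict_classifier(model, Xte[, keep, drop = FALSE])
    folds[[f]] <- tibble(fold = f, n_test = length(sp$test),
                         n_correct = sum(as.character(pred) ==
                                         as.character(y[sp$test])))
  }
  folds <- dplyr::bind_rows(folds)
  structure(
    list(accuracy = 100 * sum(folds$n_correct) / sum(folds$n_test),
         folds = dplyr::mutate(folds,
                               accuracy = 100 * .data$n_correct / .data$n_test),
         classifier = clf, scheme = val, seed = seed,
         reseeds = attr(splits, "reseeds")),
    class = "train_eval_result")
}

#' Experiment specification
#'
#' One benchmark experiment: a labeling rule, an optional balancing plan,
#' and the classifier x validation grid to sweep.
#'
#' @param labeling_rule `"systolic"`, `"diastolic"` or `"map"`; selects the
#'   label column and drops subjects that rule excludes.
#' @param balance `"none"` or `"smote"`.
#' @param balance_target target per-class size for SMOTE (`"auto"` matches
#'   the majority class).
#' @param n_original optional cap: subsample the (labeled) cohort to this
#'   many subjects before the experiment; it is an error to request more
#'   than the cohort provides.
#' @param classifiers list of [classifier_spec()] objects.
#' @param validations list of [validation_scheme()] objects.
#' @param leakage_safe if `TRUE` (default), SMOTE is fitted inside training
#'   folds only; if `FALSE` ("paper mode"), the cohort is balanced once
#'   before splitting, which lets synthetic neighbours of test subjects into
#'   training and typically inflates accuracy.
#' @param k_neighbors,variant SMOTE parameters.
#' @param seed RNG seed.
#' @return List of class `experiment_spec`.
#' @export
experiment_spec <- function(labeling_rule = c("map", "systolic", "diastolic"),
                            balance = c("none", "smote"),
                            balance_target = "auto",
                            n_original = NULL,
                            classifiers = default_classifier_grid(compact = TRUE),
                            validations = list(validation_scheme("holdout", 0.2)),
                            leakage_safe = TRUE,
                            k_neighbors = 5L,
                            variant = "standard",
                            seed = 1L) {
  structure(list(labeling_rule = match.arg(labeling_rule),
                 balance = match.arg(balance),
                 balance_target = balance_target,
                 n_original = n_original,
                 classifiers = classifiers,
                 validations = validations,
                 leakage_safe = isTRUE(leakage_safe),
                 k_neighbors = as.integer(k_neighbors),
                 variant = variant,
                 seed = as.integer(seed)),
            class = "experiment_spec")
}

rule_column <- function(rule) {
  switch(rule, systolic = "label_systolic", diastolic = "label_diastolic",
         map = "label_map")
}

smote_balance_fn <- function(k_neighbors, variant, seed) {
  function(X, y) {
    counts <- table(y)
    minority <- names(counts)[which.min(counts)]
    need <- max(counts) - min(counts)
    if (need == 0L) return(list(X = X, y = y))
    min_rows <- X[y == minority, , drop = FALSE]
    if (nrow(min_rows) <= k_neighbors) return(list(X = X, y = y))
    colnames(min_rows) <- colnames(X)
    syn <- smote(min_rows, need, k_neighbors = k_neighbors,
                 variant = variant, seed = seed)
    syn <- as.matrix(syn[, colnames(X), drop = FALSE])
    list(X = rbind(X, syn),
         y = factor(c(as.character(y), rep(minority, need)),
                    levels = levels(y)))
  }
}

#' Run a benchmark experiment
#'
#' Labels the cohort under the requested rule, optionally balances classes
#' with SMOTE (inside training folds when leakage-safe, before splitting in
#' paper mode), sweeps the classifier x validation grid, and returns a tidy
#' results table sorted by decreasing accuracy.
#'
#' @param spec an [experiment_spec()].
#' @param cohort labeled feature tibble (see [generate_cohort()]); must
#'   contain the rule's label column and the feature columns.
#' @param feature_cols feature column names (default [feature_names()]).
#' @return Tibble of class `experiment_result`: one row per grid cell with
#'   `classifier`, `kernel`, `validation`, `accuracy` (percent),
#'   `n_subjects`, `n_folds`, `reseeds`, plus attributes `labeling_rule` and
#'   `spec`. Grid cells whose fit fails (e.g. a singular covariance) carry
#'   `NA` accuracy.
#' @export
run_experiment <- function(spec, cohort, feature_cols = feature_names()) {
  stopifnot(inherits(spec, "experiment_spec"))
  col <- rule_column(spec$labeling_rule)
  if (!col %in% names(cohort))
    stop("cohort lacks label column '", col, "'", call. = FALSE)
  data <- dplyr::filter(cohort, .data[[col]] != "excluded")
  data[[col]] <- droplevels(data[[col]])
  if (!is.null(spec$n_original)) {
    if (spec$n_original > nrow(data))
      stop("experiment requests ", spec$n_original,
           " subjects but the cohort provides ", nrow(data), call. = FALSE)
    data <- local_seed(spec$seed,
                       data[sample.int(nrow(data), spec$n_original), ,
                            drop = FALSE])
  }
  balance_fn <- NULL
  if (spec$balance == "smote") {
    if (spec$leakage_safe) {
      balance_fn <- smote_balance_fn(spec$k_neighbors, spec$variant, spec$seed)
    } else {
      target <- if (identical(spec$balance_target, "auto"))
        max(table(data[[col]])) else spec$balance_target
      data <- balance_to(data, target, label = col,
                         feature_cols = feature_cols,
                         k_neighbors = spec$k_neighbors,
                         variant = spec$variant, seed = spec$seed)
    }
  }
  X <- as.matrix(data[, feature_cols])
  y <- droplevels(factor(data[[col]]))
  rows <- list()
  for (ci in seq_along(spec$classifiers)) {
    clf <- spec$classifiers[[ci]]
    for (vi in seq_along(spec$validations)) {
      val <- spec$validations[[vi]]
      res <- tryCatch(
        train_eval(X, y, clf, val,
                   balance_fn = balance_fn,
                   seed = spec$seed + 97L * ci + vi),
        error = function(e) e)
      failed <- inherits(res, "error")
      rows[[length(rows) + 1L]] <- tibble(
        classifier = clf$family,
        kernel = clf$kernel,
        validation = scheme_label(val),
        accuracy = if (failed) NA_real_ else res$accuracy,
        n_subjects = nrow(X),
        n_folds = if (failed) NA_integer_ else nrow(res$folds),
        reseeds = if (failed) NA_integer_ else res$reseeds,
        note = if (failed) conditionMessage(res) else NA_character_)
    }
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$accuracy))
  attr(out, "labeling_rule") <- spec$labeling_rule
  attr(out, "spec") <- spec
  class(out) <- c("experiment_result", class(out))
  out
}

#' Compare labeling rules
#'
#' Extracts the best-accuracy row of each completed experiment into a
#' three-row summary, optionally restricted to one classifier family so the
#' rules are compared like-for-like. Ties for the best accuracy within a
#' rule are all reported and flagged.
#'
#' @param results named list of [run_experiment()] tables; names (or their
#'   `labeling_rule` attributes) identify the rules.
#' @param family optional classifier family to restrict to (e.g. `"svm"`).
#' @return Tibble with `rule`, `classifier`, `kernel`, `validation`,
#'   `accuracy`, `tied`.
#' @export
compare_rules <- function(results, family = NULL) {
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- vapply(results, function(r)
      attr(r, "labeling_rule") %||% NA_character_, character(1))
  purrr::map_dfr(names(results), function(nm) {
    r <- results[[nm]]
    if (!is.null(family)) r <- dplyr::filter(r, .data$classifier == family)
    r <- dplyr::filter(r, !is.na(.data$accuracy))
    if (nrow(r) == 0L)
      return(tibble(rule = nm, classifier = NA_character_,
                    kernel = NA_character_, validation = NA_character_,
                    accuracy = NA_real_, tied = FALSE))
    best <- max(r$accuracy)
    top <- dplyr::filter(r, .data$accuracy == best)
    tibble(rule = nm, classifier = top$classifier, kernel = top$kernel,
           validation = top$validation, accuracy = top$accuracy,
           tied = nrow(top) > 1L)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
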