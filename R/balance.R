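#' SMOTE: synthetic minority over-sampling
#'
#' Generates synthetic minority-class samples in feature space. The
#' `standard` variant interpolates between a random minority point `x` and
#' one of its `k` nearest minority neighbours: `x + lambda (x_nn - x)` with
#' `lambda ~ U(0, 1)`. The `weighted_accumulation` variant instead draws one
#' random weight per contributor (the point plus its `k` neighbours),
#' normalises the weights to sum to 1, and accumulates the weighted feature
#' vectors, so each synthetic sample lies in the convex hull of its `k + 1`
#' contributors.
#'
#' @param minority numeric matrix or data frame of minority-class feature
#'   vectors (rows = samples); must have more rows than `k_neighbors`.
#' @param n_synthetic number of samples to generate, or `"auto"` together
#'   with `majority_n` to top the minority up to the majority size.
#' @param k_neighbors number of nearest neighbours considered (default 5).
#' @param variant `"standard"` or `"weighted_accumulation"`.
#' @param majority_n majority class size, used only with
#'   `n_synthetic = "auto"`.
#' @param seed integer RNG seed; output is reproducible.
#' @return Tibble of synthetic samples with the minority's column names and
#'   a `source = "synthetic"` column.
#' @export
smote <- function(minority, n_synthetic, k_neighbors = 5L,
                  variant = c("standard", "weighted_accumulation"),
                  majority_n = NULL, seed = 1L) {
  variant <- match.arg(variant)
  x <- as.matrix(minority)
  if (!is.numeric(x)) stop("minority features must be numeric", call. = FALSE)
  n <- nrow(x)
  if (n <= k_neighbors)
    stop("minority size (", n, ") must exceed k_neighbors (", k_neighbors, ")",
         call. = FALSE)
  if (identical(n_synthetic, "auto")) {
    if (is.null(majority_n))
      stop("n_synthetic = \"auto\" requires majority_n", call. = FALSE)
    n_synthetic <- max(0L, majority_n - n)
  }
  n_synthetic <- as.integer(n_synthetic)
  if (n_synthetic < 0L) stop("n_synthetic must be >= 0", call. = FALSE)
  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("f", seq_len(ncol(x)))
  if (n_synthetic == 0L) {
    out <- as_tibble(matrix(numeric(0), 0, ncol(x), dimnames = list(NULL, cn)))
    out$source <- character(0)
    return(out)
  }
  dm <- as.matrix(stats::dist(x))
  diag(dm) <- Inf
  nn_idx <- t(apply(dm, 1, function(r) order(r)[seq_len(k_neighbors)]))
  local_seed(seed, {
    base <- sample.int(n, n_synthetic, replace = TRUE)
    synth <- matrix(NA_real_, n_synthetic, ncol(x))
    for (i in seq_len(n_synthetic)) {
      b <- base[i]
      if (variant == "standard") {
        nb <- nn_idx[b, sample.int(k_neighbors, 1L)]
        lambda <- runif(1)
        synth[i, ] <- x[b, ] + lambda * (x[nb, ] - x[b, ])
      } else {
        contrib <- c(b, nn_idx[b, ])
        w <- runif(k_neighbors + 1L)
        w <- w / sum(w)
        synth[i, ] <- as.vector(w %*% x[contrib, , drop = FALSE])
      }
    }
    colnames(synth) <- cn
    out <- as_tibble(synth)
    out$source <- "synthetic"
    out
  })
}

#' Oversample a labeled cohort to equal class sizes
#'
#' Applies [smote()] to each binary class of a labeled feature table until
#' both classes reach the target size. Rows labeled `excluded` under the
#' chosen rule are dropped first. Synthetic rows carry the class label and
#' features; subject-level columns that have no meaning for synthetic
#' samples (readings, pressures) are left `NA`.
#'
#' @param cohort labeled feature tibble (e.g. from [generate_cohort()]).
#' @param n_per_class target size for each class; a single number or a
#'   length-2 vector `c(normotensive, hypertensive)`. Must be at least the
#'   current class sizes.
#' @param label name of the label column to balance on
#'   (default `"label_map"`).
#' @param feature_cols feature column names (default [feature_names()]).
#' @param k_neighbors,variant,seed passed to [smote()].
#' @return Tibble with original plus synthetic rows; class counts under
#'   `label` are exactly `n_per_class`.
#' @export
balance_to <- function(cohort, n_per_class, label = "label_map",
                       feature_cols = feature_names(), k_neighbors = 5L,
                       variant = "standard", seed = 1L) {
  if (!label %in% names(cohort)) stop("no column '", label, "'", call. = FALSE)
  if (!all(feature_cols %in% names(cohort)))
    stop("cohort lacks feature columns", call. = FALSE)
  cohort <- dplyr::filter(cohort, .data[[label]] != "excluded")
  classes <- c("normotensive", "hypertensive")
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, 2L)
  n_per_class <- setNames(as.integer(n_per_class), classes)
  out <- list(as_tibble(cohort))
  for (i in seq_along(classes)) {
    cls <- classes[i]
    rows <- cohort[cohort[[label]] == cls, , drop = FALSE]
    cur <- nrow(rows)
    if (cur > n_per_class[cls])
      stop("target for ", cls, " (", n_per_class[cls],
           ") is below current size (", cur, ")", call. = FALSE)
    need <- n_per_class[cls] - cur
    if (need == 0L) next
    synth <- smote(rows[, feature_cols], need, k_neighbors = k_neighbors,
                   variant = variant, seed = seed + i)
    add <- tibble(subject_id = sprintf("SYN-%s-%03d", substr(cls, 1, 4),
                                       seq_len(need)))
    add[[label]] <- label_factor(rep(cls, need))
    if ("class" %in% names(cohort))
      add$class <- factor(rep(cls, need),
                          levels = c("normotensive", "hypertensive"))
    add$source <- "synthetic"
    add <- dplyr::bind_cols(add, synth[, feature_cols])
    out[[length(out) + 1L]] <- add
  }
  dplyr::bind_rows(out)
}
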