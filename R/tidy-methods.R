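# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @export
tidy.experiment_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @export
glance.experiment_result <- function(x, ...) {
  ok <- x[!is.na(x$accuracy), ]
  tibble(labeling_rule = attr(x, "labeling_rule") %||% NA_character_,
         n_grid = nrow(x),
         n_failed = sum(is.na(x$accuracy)),
         n_subjects = if (nrow(x)) x$n_subjects[1] else NA_integer_,
         best_accuracy = if (nrow(ok)) max(ok$accuracy) else NA_real_,
         best_classifier = if (nrow(ok)) ok$classifier[which.max(ok$accuracy)]
                           else NA_character_)
}

#' @export
tidy.train_eval_result <- function(x, ...) x$folds

#' @export
glance.train_eval_result <- function(x, ...) {
  tibble(classifier = x$classifier$family, kernel = x$classifier$kernel,
         validation = scheme_label(x$scheme), accuracy = x$accuracy,
         n_folds = nrow(x$folds), reseeds = x$reseeds)
}

#' @export
tidy.intensity_model <- function(x, ...) {
  tibble(component = c("vessel", "tissue"),
         mean = c(x$mu_b, x$mu_o),
         sd = c(x$sigma_b, x$sigma_o),
         weight = c(x$weight_b, 1 - x$weight_b))
}

#' @export
glance.intensity_model <- function(x, ...) {
  tibble(mu_b = x$mu_b, mu_o = x$mu_o, threshold = separation_threshold(x),
         loglik = tail(x$loglik, 1), em_iterations = length(x$loglik))
}

#' @export
tidy.radii_distribution <- function(x, ...) {
  tibble(threshold = 1:11, cdf = x$cdf_bins, pdf = x$pdf_bins)
}

#' @export
glance.radii_distribution <- function(x, ...) {
  tibble(n_skeleton = x$n_skeleton,
         radius_median = median(x$radii),
         radius_mean = mean(x$radii),
         radius_max = max(x$radii))
}

#' @export
autoplot.experiment_result <- function(object, ...) {
  df <- tidy(object)
  df$label <- paste(df$classifier, df$kernel, sep = "\n")
  ggplot2::ggplot(df[!is.na(df$accuracy), ],
                  ggplot2::aes(x = stats::reorder(.data$label, .data$accuracy),
                               y = .data$accuracy,
                               fill = .data$validation)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Accuracy (%)",
                  fill = "Validation",
                  title = paste("Labeling rule:",
                                attr(object, "labeling_rule") %||% "")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.radii_distribution <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$cdf)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Radius threshold (voxels)", y = "CDF") +
    ggplot2::theme_minimal()
}

#' Blood-pressure scatter of a labeled cohort
#'
#' SBP against DBP, coloured by the MAP-rule label, with the guideline
#' reference lines at 120/80 mmHg.
#'
#' @param cohort labeled cohort tibble.
#' @return A ggplot object.
#' @export
plot_bp_cohort <- function(cohort) {
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data$sbp, y = .data$dbp,
                                       colour = .data$label_map)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 120, linetype = 2, colour = "grey50") +
    ggplot2::geom_hline(yintercept = 80, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "Resting SBP (mmHg)", y = "Resting DBP (mmHg)",
                  colour = "MAP label") +
    ggplot2::theme_minimal()
}
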