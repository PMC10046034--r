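#' Preprocessing parameters
#'
#' Controls the three cleaning stages applied before segmentation: a
#' low-order multiplicative bias-field fit on log-intensities, an
#' edge-preserving generalized-Gaussian neighbourhood smoother, and
#' threshold-based brain-mask extraction.
#'
#' @param bias_fit_order polynomial order of the log-intensity bias fit
#'   (1 or 2; 2 captures linear and quadratic shading).
#' @param smooth_iterations gradient steps of the smoother.
#' @param smooth_beta shape exponent of the neighbourhood penalty in (1, 2];
#'   2 is a quadratic (Gaussian-like) penalty, values toward 1 preserve
#'   edges more strongly.
#' @param smooth_lambda weight of the neighbourhood penalty relative to the
#'   data term (dimensionless; intensities are standardized internally).
#' @param mask_threshold_quantile fraction in (0, 1) placing the brain-mask
#'   threshold between the volume minimum and its 99.9th percentile.
#' @return List of class `preprocess_params`.
#' @export
preprocess_params <- function(bias_fit_order = 2L,
                              smooth_iterations = 8L,
                              smooth_beta = 1.5,
                              smooth_lambda = 0.5,
                              mask_threshold_quantile = 0.4) {
  if (bias_fit_order < 1L) stop("bias_fit_order must be >= 1", call. = FALSE)
  if (smooth_iterations < 1L) stop("smooth_iterations must be >= 1", call. = FALSE)
  if (smooth_beta <= 1 || smooth_beta > 2)
    stop("smooth_beta must be in (1, 2]", call. = FALSE)
  if (mask_threshold_quantile <= 0 || mask_threshold_quantile >= 1)
    stop("mask_threshold_quantile must be in (0, 1)", call. = FALSE)
  structure(
    list(bias_fit_order = as.integer(bias_fit_order),
         smooth_iterations = as.integer(smooth_iterations),
         smooth_beta = smooth_beta,
         smooth_lambda = smooth_lambda,
         mask_threshold_quantile = mask_threshold_quantile),
    class = "preprocess_params")
}

poly_design <- function(x, y, z, order) {
  cols <- list(intercept = rep(1, length(x)), x = x, y = y, z = z)
  if (order >= 2L) {
    cols <- c(cols, list(xy = x * y, xz = x * z, yz = y * z,
                         x2 = x^2, y2 = y^2, z2 = z^2))
  }
  do.call(cbind, cols)
}

#' Multiplicative bias-field correction
#'
#' Fits a smooth low-order polynomial to the log-intensities (optionally
#' restricted to a mask, e.g. the brain), divides the corresponding
#' multiplicative field out of the volume, and rescales so that the output
#' mean intensity equals the input mean.
#'
#' @param volume 3-D numeric array; intensities are floored at a small
#'   positive value before taking logs.
#' @param params a [preprocess_params()] object.
#' @param mask optional binary array: voxels used to fit the field (the
#'   correction is applied to the whole volume).
#' @return Corrected volume with attribute `bias_field` (the removed field,
#'   mean 1).
#' @export
correct_bias <- function(volume, params = preprocess_params(), mask = NULL) {
  assert_finite_volume(volume)
  d <- dim(volume)
  # The log-fit needs positive values; clamping (rather than shifting the
  # whole volume) keeps log(signal * field) linear in the field, so the
  # polynomial recovers the multiplicative structure. Fit voxels should be
  # genuine tissue (pass a brain mask when the volume contains air).
  floor_val <- 1e-3 * max(abs(volume))
  v <- pmax(volume, floor_val)
  xs <- seq(-1, 1, length.out = d[1])
  ys <- seq(-1, 1, length.out = d[2])
  zs <- seq(-1, 1, length.out = d[3])
  X <- array(rep(xs, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(zs, each = d[1] * d[2]), dim = d)
  fit_idx <- if (is.null(mask)) seq_along(v) else which(as_binary_array(mask))
  if (length(fit_idx) < 20L) stop("too few voxels to fit a bias field", call. = FALSE)
  if (length(fit_idx) > 60000L)  # deterministic stride subsample
    fit_idx <- fit_idx[seq(1L, length(fit_idx),
                           by = ceiling(length(fit_idx) / 60000L))]
  D <- poly_design(X[fit_idx], Y[fit_idx], Z[fit_idx], params$bias_fit_order)
  beta <- qr.coef(qr(D), log(v[fit_idx]))
  beta[is.na(beta)] <- 0
  Dall <- poly_design(as.vector(X), as.vector(Y), as.vector(Z),
                      params$bias_fit_order)
  field <- exp(array(Dall %*% beta, dim = d))
  # normalise over the fitted region and clamp the extrapolated tails so the
  # correction stays a gentle multiplicative reshaping everywhere
  region <- if (is.null(mask)) TRUE else as_binary_array(mask)
  field <- field / mean(field[region])
  field <- pmin(pmax(field, 0.25), 4)
  out <- volume / field
  out <- out + (mean(volume[region]) - mean(out[region]))
  attr(out, "bias_field") <- field
  out
}

#' Edge-preserving neighbourhood smoothing
#'
#' Iterative MAP-style smoothing with a generalized-Gaussian penalty on
#' 6-neighbour intensity differences: energy
#' `sum (x - y)^2 / 2 + lambda * sum |x_i - x_j|^beta` minimised by gradient
#' descent on standardized intensities. `beta = 2` reduces to a linear
#' (Gaussian-like) smoother; smaller exponents penalise large jumps less,
#' preserving step edges while flattening noise.
#'
#' @param volume 3-D numeric array (finite).
#' @param params a [preprocess_params()] object.
#' @return Smoothed volume, same shape.
#' @export
ggmrf_smooth <- function(volume, params = preprocess_params()) {
  assert_finite_volume(volume)
  m <- mean(volume); s <- sd(volume)
  if (s == 0) return(volume)  # constant volumes are a fixed point
  zy <- (volume - m) / s
  z <- zy
  beta <- params$smooth_beta
  lambda <- params$smooth_lambda
  offs <- neighbourhood_offsets(6L)
  step <- 0.4 / (1 + 6 * lambda * beta)
  for (it in seq_len(params$smooth_iterations)) {
    pen <- array(0, dim = dim(z))
    for (i in seq_len(nrow(offs))) {
      nb <- shift_array(z, offs$dx[i], offs$dy[i], offs$dz[i], fill = NA)
      df <- z - nb
      df[is.na(df)] <- 0
      pen <- pen + sign(df) * abs(df)^(beta - 1)
    }
    z <- z - step * ((z - zy) + lambda * beta * pen)
  }
  z * s + m
}

#' Brain-mask extraction
#'
#' Thresholds the volume between its minimum and 99.9th percentile, keeps
#' the largest 26-connected component, closes it morphologically and fills
#' interior holes, yielding a single connected head/brain mask that contains
#' the bright vasculature.
#'
#' @param volume 3-D numeric array (finite).
#' @param params a [preprocess_params()] object.
#' @return Logical array of the same shape (exactly one connected component).
#' @export
strip_skull <- function(volume, params = preprocess_params()) {
  assert_finite_volume(volume)
  qlo <- min(volume)
  qhi <- quantile(volume, 0.999, names = FALSE)
  thr <- qlo + params$mask_threshold_quantile * (qhi - qlo)
  mask <- array(volume >= thr, dim = dim(volume))
  if (!any(mask)) stop("brain mask is empty", call. = FALSE)
  mask <- largest_component(mask, 26L)
  mask <- close6(mask, 2L)
  # fill interior holes: background components not touching the boundary
  bg <- label_components(!mask, 6L)
  if (max(bg) > 0L) {
    d <- dim(mask)
    border_labels <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                              bg[, , 1], bg[, , d[3]]))
    hole <- bg > 0L & !(bg %in% border_labels)
    mask[hole] <- TRUE
  }
  largest_component(mask, 26L)
}

#' Full preprocessing chain
#'
#' Brain-mask extraction on the raw volume, bias correction fitted within
#' the mask, then edge-preserving smoothing.
#'
#' @param volume 3-D numeric array.
#' @param params a [preprocess_params()] object.
#' @return List with `volume` (bias-corrected and smoothed), `model_volume`
#'   (bias-corrected only — intensity-model fits behave better before
#'   smoothing, whose edge spillover makes the tissue marginal heavy-tailed),
#'   `brain_mask`, and `params`.
#' @export
preprocess_volume <- function(volume, params = preprocess_params()) {
  brain <- strip_skull(volume, params)
  v <- correct_bias(volume, params, mask = brain)
  attr(v, "bias_field") <- NULL
  sm <- ggmrf_smooth(v, params)
  list(volume = sm, model_volume = v, brain_mask = brain, params = params)
}
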