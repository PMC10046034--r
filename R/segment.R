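#' Two-population intensity model
#'
#' Fits a two-component univariate Gaussian mixture to the (masked) voxel
#' intensities by expectation-maximization: a bright vessel population
#' (`mu_b`) and a darker tissue population (`mu_o`), with
#' `mu_b > mu_o` by convention regardless of initialization. Component SDs
#' are floored at a small fraction of the intensity range so that noiseless
#' two-valued volumes converge instead of collapsing.
#'
#' @param volume 3-D numeric array.
#' @param brain_mask optional binary array restricting the fit (e.g. from
#'   [strip_skull()]); air outside the head would otherwise form a third
#'   population.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @param max_voxels deterministic stride subsample cap for the fit.
#' @return Object of class `intensity_model`: `mu_b`, `mu_o`, `sigma_b`,
#'   `sigma_o`, `weight_b`, and the per-iteration `loglik` trace
#'   (non-decreasing).
#' @export
fit_intensity_model <- function(volume, brain_mask = NULL, max_iter = 300L,
                                tol = 1e-9, max_voxels = 200000L) {
  assert_finite_volume(volume)
  vals <- if (is.null(brain_mask)) as.vector(volume)
          else volume[as_binary_array(brain_mask)]
  if (length(vals) == 0L) stop("brain mask is empty", call. = FALSE)
  rng <- diff(range(vals))
  if (rng == 0)
    stop("degenerate input: all masked voxels share one intensity",
         call. = FALSE)
  if (length(vals) > max_voxels)
    vals <- vals[seq(1L, length(vals), by = ceiling(length(vals) / max_voxels))]
  sd_floor <- 1e-3 * rng

  # robust init: tissue from the bulk (median / MAD), vessels from the top
  # half-percent tail, so the rare bright population is not swallowed
  q995 <- quantile(vals, 0.995, names = FALSE)
  top <- vals[vals >= q995]
  mu <- c(median(vals), mean(top))
  if (mu[1] >= mu[2]) mu <- range(vals)
  sig <- pmax(c(mad(vals), sd(top)), sd_floor)
  sig[!is.finite(sig)] <- sd_floor
  w <- c(0.995, 0.005)
  loglik <- numeric(0)
  for (it in seq_len(max_iter)) {
    ld1 <- log(w[1]) + dnorm(vals, mu[1], sig[1], log = TRUE)
    ld2 <- log(w[2]) + dnorm(vals, mu[2], sig[2], log = TRUE)
    mx <- pmax(ld1, ld2)
    lse <- mx + log(exp(ld1 - mx) + exp(ld2 - mx))
    loglik <- c(loglik, sum(lse))
    r2 <- exp(ld2 - lse)
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(r1 * vals) / n1, sum(r2 * vals) / n2)
    sig <- pmax(c(sqrt(sum(r1 * (vals - mu[1])^2) / n1),
                  sqrt(sum(r2 * (vals - mu[2])^2) / n2)), sd_floor)
    w <- c(n1, n2) / length(vals)
    if (it > 1 && abs(loglik[it] - loglik[it - 1]) <
        tol * (abs(loglik[it - 1]) + 1e-12)) break
  }
  bright <- which.max(mu)
  dark <- 3L - bright
  structure(
    list(mu_b = mu[bright], mu_o = mu[dark],
         sigma_b = sig[bright], sigma_o = sig[dark],
         weight_b = w[bright], loglik = loglik),
    class = "intensity_model")
}

#' @export
print.intensity_model <- function(x, ...) {
  cat(sprintf("<intensity_model> vessels %.2f +/- %.2f (w = %.3f); tissue %.2f +/- %.2f\n",
              x$mu_b, x$sigma_b, x$weight_b, x$mu_o, x$sigma_o))
  invisible(x)
}

#' Global separation threshold
#'
#' The midpoint `T = (mu_b + mu_o) / 2` between the vessel and tissue mean
#' intensities.
#'
#' @param model an `intensity_model` (or anything with `mu_b`, `mu_o`).
#' @return Numeric threshold.
#' @export
separation_threshold <- function(model) (model$mu_b + model$mu_o) / 2

#' Initial vasculature delineation
#'
#' Classifies each voxel by comparing the two mixture components'
#' (log-)posteriors: a voxel joins the initial vessel mask iff its vessel
#' posterior is at least the tissue posterior. Deterministic; with equal
#' variances and weights the decision boundary is exactly the midpoint
#' threshold.
#'
#' @param volume 3-D numeric array.
#' @param model an [fit_intensity_model()] result.
#' @param brain_mask optional binary array; voxels outside are never vessel.
#' @return Logical array.
#' @export
initial_segmentation <- function(volume, model, brain_mask = NULL) {
  assert_finite_volume(volume)
  ld_b <- log(model$weight_b) + dnorm(volume, model$mu_b, model$sigma_b, log = TRUE)
  ld_o <- log(1 - model$weight_b) + dnorm(volume, model$mu_o, model$sigma_o, log = TRUE)
  mask <- array(ld_b >= ld_o, dim = dim(volume))
  if (!is.null(brain_mask)) mask <- mask & as_binary_array(brain_mask)
  mask
}

slice_components <- function(slice_mask) {
  d2 <- dim(slice_mask)
  lab <- .cpp_label_components(as.logical(slice_mask),
                               c(as.integer(d2), 1L), 26L)  # 8-connectivity in-plane
  matrix(lab, d2[1], d2[2])
}

#' Adaptive local refinement of the initial mask
#'
#' Works slice by slice (axial planes): the initial mask in each slice is
#' split into 8-connected components; around each component a search window
#' (its bounding box dilated by `window_growth` times the component's
#' equivalent diameter) defines a local vessel mean `mu_b` (in-mask window
#' voxels) and tissue mean `mu_o` (out-of-mask window voxels), and window
#' voxels brighter than the local midpoint threshold `(mu_b + mu_o) / 2`
#' are added to the mask. Components whose window has no out-of-mask voxels
#' are skipped and logged. The refined mask always contains the initial one.
#'
#' @param volume 3-D numeric array.
#' @param initial_mask logical array from [initial_segmentation()].
#' @param window_growth window dilation as a multiple of the component
#'   equivalent diameter (default 1).
#' @return List with `mask` (refined), `local_thresholds` (tibble: slice,
#'   component, window bounds, local means, threshold, voxels added) and
#'   `skipped` (count of windows without background voxels).
#' @export
adaptive_refine <- function(volume, initial_mask, window_growth = 1.0) {
  assert_finite_volume(volume)
  initial_mask <- as_binary_array(initial_mask)
  stopifnot(all(dim(volume) == dim(initial_mask)))
  if (window_growth <= 0) stop("window_growth must be positive", call. = FALSE)
  d <- dim(volume)
  refined <- initial_mask
  recs <- list()
  skipped <- 0L
  for (z in seq_len(d[3])) {
    sl <- initial_mask[, , z]
    if (!any(sl)) next
    lab <- slice_components(sl)
    vol_sl <- volume[, , z]
    for (comp in seq_len(max(lab))) {
      idx <- which(lab == comp, arr.ind = TRUE)
      area <- nrow(idx)
      d_eq <- 2 * sqrt(area / pi)
      g <- ceiling(window_growth * d_eq)
      x0 <- max(1L, min(idx[, 1]) - g); x1 <- min(d[1], max(idx[, 1]) + g)
      y0 <- max(1L, min(idx[, 2]) - g); y1 <- min(d[2], max(idx[, 2]) + g)
      win_vals <- vol_sl[x0:x1, y0:y1]
      win_mask <- sl[x0:x1, y0:y1]
      if (all(win_mask)) { skipped <- skipped + 1L; next }
      mu_b_loc <- mean(win_vals[win_mask])
      mu_o_loc <- mean(win_vals[!win_mask])
      thr <- (mu_b_loc + mu_o_loc) / 2
      add <- !win_mask & win_vals > thr
      if (any(add)) {
        sub <- refined[x0:x1, y0:y1, z]
        refined[x0:x1, y0:y1, z] <- sub | add
      }
      recs[[length(recs) + 1L]] <- tibble(
        slice = z, component = comp,
        x0 = x0, x1 = x1, y0 = y0, y1 = y1,
        mu_b = mu_b_loc, mu_o = mu_o_loc, threshold = thr,
        n_added = sum(add))
    }
  }
  list(mask = refined,
       local_thresholds = if (length(recs)) dplyr::bind_rows(recs)
                          else tibble(slice = integer(), component = integer(),
                                      x0 = integer(), x1 = integer(),
                                      y0 = integer(), y1 = integer(),
                                      mu_b = double(), mu_o = double(),
                                      threshold = double(), n_added = integer()),
       skipped = skipped)
}

#' Seed generation for region growing
#'
#' Every refined-mask voxel is a seed. In addition, the window scan of
#' [adaptive_refine()] is repeated on the refined mask, and out-of-mask
#' voxels exceeding their window's local threshold are appended as candidate
#' seeds — these flag regions likely to hold small vessels that the mask
#' still misses.
#'
#' @param volume 3-D numeric array.
#' @param refined_mask logical array.
#' @param window_growth as in [adaptive_refine()].
#' @return Integer vector of seed linear indices (1-based), with attribute
#'   `candidates` marking which entries came from the window scan.
#' @export
generate_seeds <- function(volume, refined_mask, window_growth = 1.0) {
  refined_mask <- as_binary_array(refined_mask)
  base <- which(refined_mask)
  scan <- adaptive_refine(volume, refined_mask, window_growth)
  extra <- setdiff(which(scan$mask), base)
  seeds <- c(base, extra)
  attr(seeds, "candidates") <- c(rep(FALSE, length(base)),
                                 rep(TRUE, length(extra)))
  seeds
}

#' 3-D region growing from seeds
#'
#' Breadth-first growth over the 26-neighbourhood starting at the seed
#' voxels, accepting voxels whose intensity strictly exceeds the global
#' midpoint threshold of the intensity model. Grown components smaller than
#' `min_component_size` voxels are discarded.
#'
#' @param volume 3-D numeric array.
#' @param seeds integer vector of seed linear indices.
#' @param model an [fit_intensity_model()] result (supplies the threshold).
#' @param min_component_size minimum voxels a component must have (default 5).
#' @param connectivity 26 (default) or 6.
#' @return Logical array: the final vasculature mask.
#' @export
region_grow_3d <- function(volume, seeds, model, min_component_size = 5L,
                           connectivity = 26L) {
  assert_finite_volume(volume)
  if (length(seeds) == 0L) stop("no seeds supplied", call. = FALSE)
  d <- dim(volume)
  thr <- separation_threshold(model)
  grown <- .cpp_region_grow(as.numeric(volume), as.integer(d),
                            as.integer(seeds - 1L), thr,
                            as.integer(connectivity))
  grown <- array(grown, dim = d)
  if (min_component_size > 1L && any(grown)) {
    lab <- label_components(grown, connectivity)
    counts <- tabulate(lab[lab > 0L])
    keep <- which(counts >= min_component_size)
    grown <- array(lab %in% keep & lab > 0L, dim = d)
  }
  grown
}

#' Full segmentation chain
#'
#' Intensity-model fit, posterior-based initial delineation, slice-wise
#' adaptive refinement, seed generation and 3-D region growing.
#'
#' @param volume cleaned 3-D numeric array.
#' @param brain_mask optional binary array restricting the model fit and
#'   initial mask.
#' @param model_volume optional volume used only for the intensity-model
#'   fit (e.g. the bias-corrected but unsmoothed volume from
#'   [preprocess_volume()], whose marginal is closer to a two-Gaussian
#'   mixture); defaults to `volume`.
#' @param window_growth see [adaptive_refine()].
#' @param min_component_size see [region_grow_3d()].
#' @return Object of class `segmentation_result`: `initial_mask`,
#'   `refined_mask`, `final_mask`, `seeds`, `local_thresholds`, `model`.
#' @export
segment_vessels <- function(volume, brain_mask = NULL, model_volume = NULL,
                            window_growth = 1.0, min_component_size = 5L) {
  model <- fit_intensity_model(model_volume %||% volume, brain_mask)
  initial <- initial_segmentation(volume, model, brain_mask)
  ref <- adaptive_refine(volume, initial, window_growth)
  seeds <- generate_seeds(volume, ref$mask, window_growth)
  final <- region_grow_3d(volume, seeds, model, min_component_size)
  structure(
    list(initial_mask = initial, refined_mask = ref$mask, final_mask = final,
         seeds = seeds, local_thresholds = ref$local_thresholds,
         model = model),
    class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result>",
      sum(x$initial_mask), "initial /", sum(x$refined_mask), "refined /",
      sum(x$final_mask), "final vessel voxels; T =",
      round(separation_threshold(x$model), 2), "\n")
  invisible(x)
}

#' Overlap metrics between predicted and true masks
#'
#' Dice = 2|P∩T| / (|P| + |T|), sensitivity = |P∩T| / |T|, specificity =
#' true-negative rate, all reported as percentages.
#'
#' @param pred,truth same-shape binary arrays.
#' @return One-row tibble with `dice`, `sensitivity`, `specificity` (percent).
#' @export
evaluate_segmentation <- function(pred, truth) {
  pred <- as_binary_array(pred, "pred")
  truth <- as_binary_array(truth, "truth")
  stopifnot(all(dim(pred) == dim(truth)))
  if (!any(truth))
    stop("truth mask is empty: sensitivity undefined", call. = FALSE)
  tp <- sum(pred & truth)
  tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth)
  tibble(
    dice = 100 * 2 * tp / (sum(pred) + sum(truth)),
    sensitivity = 100 * tp / sum(truth),
    specificity = 100 * tn / (tn + fp))
}
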