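#' Euclidean distance map
#'
#' Exact Euclidean distance transform of a binary mask: each foreground
#' voxel's centre-to-centre distance to the nearest background voxel, and 0
#' outside the mask. Evaluated at a vessel centerline this approximates the
#' local vessel radius.
#'
#' @param mask binary 3-D array (non-empty).
#' @return Numeric array of distances (voxels).
#' @export
distance_map <- function(mask) {
  mask <- as_binary_array(mask)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  d <- dim(mask)
  array(.cpp_edt(as.logical(mask), as.integer(d)), dim = d)
}

#' Distance-ridge skeleton
#'
#' Centerline approximation of a tubular mask: foreground voxels whose
#' distance-map value is maximal over their 26-neighbourhood
#' (plateau-inclusive). On straight tubes this is the medial axis; on noisy
#' masks it is a thin ridge adequate for radius sampling.
#'
#' @param mask binary 3-D array.
#' @param edt optional precomputed [distance_map()] of `mask`.
#' @return Logical array marking skeleton voxels.
#' @export
skeletonize_mask <- function(mask, edt = NULL) {
  mask <- as_binary_array(mask)
  if (is.null(edt)) edt <- distance_map(mask)
  ridge <- mask & (edt >= neighbourhood_max(edt) - 1e-9)
  if (!any(ridge)) stop("mask skeletonizes to empty", call. = FALSE)
  ridge
}

#' Bin radii at integer thresholds
#'
#' `cdf[j]` is the fraction of radii at most `j + 0.5` voxels — the
#' half-voxel tolerance assigns each radius to its nearest integer bin and
#' absorbs the upward lattice quantization of distance-map estimates (the
#' nearest background lattice point overshoots the true radius by up to
#' ~0.25 voxels). Radii beyond the last threshold accumulate there, so the
#' CDF terminates at exactly 1.
#'
#' @param radii numeric vector of radii (voxels).
#' @return Numeric CDF vector of length 11.
#' @keywords internal
radius_cdf_bins <- function(radii) {
  cdf <- vapply(1:11, function(j) mean(radii <= j + 0.5), numeric(1))
  cdf[11] <- 1
  cdf
}

#' Vascular radius distribution
#'
#' Samples the distance map at skeleton voxels (so thick vessels are not
#' over-weighted by their volume) and bins the resulting radii at integer
#' thresholds 1..11 voxels (see [radius_cdf_bins()]). `pdf` holds the
#' per-bin increments.
#'
#' @param mask binary 3-D array.
#' @return Object of class `radii_distribution`: `radii` (per skeleton
#'   point), `cdf_bins`, `pdf_bins` (each length 11, unpadded), and the
#'   skeleton voxel count.
#' @export
extract_radii <- function(mask) {
  mask <- as_binary_array(mask)
  edt <- distance_map(mask)
  skel <- skeletonize_mask(mask, edt)
  radii <- edt[skel]
  cdf <- radius_cdf_bins(radii)
  structure(
    list(radii = radii,
         cdf_bins = cdf,
         pdf_bins = diff(c(0, cdf)),
         n_skeleton = sum(skel)),
    class = "radii_distribution")
}

#' Zero-pad a radius CDF
#'
#' Storage convention for the 11 CDF bins of the feature vector: every entry
#' after the first bin that reaches 1 is stored as 0 (the trailing 1s carry
#' no information once the distribution has saturated).
#'
#' @param cdf_bins non-decreasing numeric vector ending at 1.
#' @return Same length vector with entries after the first 1 replaced by 0.
#' @examples
#' zero_pad_cdf(c(0.4, 0.9, 0.9997, 1, 1))   # last entry becomes 0
#' @export
zero_pad_cdf <- function(cdf_bins) {
  if (any(diff(cdf_bins) < -1e-9))
    stop("cdf_bins must be non-decreasing", call. = FALSE)
  if (abs(cdf_bins[length(cdf_bins)] - 1) > 1e-6)
    stop("cdf_bins must terminate at 1", call. = FALSE)
  first_one <- which(cdf_bins >= 1 - 1e-9)[1]
  out <- cdf_bins
  if (!is.na(first_one) && first_one < length(out))
    out[(first_one + 1):length(out)] <- 0
  out
}

central_diff <- function(f, axis) {
  sh <- function(s) switch(axis,
                           shift_array(f, s, 0, 0),
                           shift_array(f, 0, s, 0),
                           shift_array(f, 0, 0, s))
  (sh(-1) - sh(1)) / 2
}

#' Principal surface curvatures of a binary mask
#'
#' The mask is presmoothed into an implicit function F (Gaussian, SD
#' `presmooth_sd` voxels); at each surface voxel (mask voxels with a
#' background 6-neighbour) the principal curvatures are computed from the
#' gradient and Hessian of F with the standard implicit-surface formulas, so
#' mean curvature is `(k1 + k2) / 2` and Gaussian curvature `k1 * k2`.
#' Convex bright structures have positive mean curvature under the
#' outward-normal convention (a sphere of radius R gives `1/R`, `1/R^2`).
#' Points with vanishing gradient are skipped.
#'
#' @param mask binary 3-D array with at least one surface voxel.
#' @param presmooth_sd Gaussian presmoothing SD (voxels, default 1).
#' @return Tibble with one row per retained surface voxel: `x`, `y`, `z`,
#'   `k1`, `k2` (`k1 >= k2`), `mean_curv`, `gauss_curv`; attribute
#'   `n_skipped` counts the vanishing-gradient points.
#' @export
surface_curvatures <- function(mask, presmooth_sd = 1) {
  mask <- as_binary_array(mask)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  surf <- mask & !erode6(mask)
  if (!any(surf)) stop("mask has no surface voxels", call. = FALSE)
  F <- gaussian_smooth(array(as.numeric(mask), dim = dim(mask)), presmooth_sd)

  gx <- central_diff(F, 1); gy <- central_diff(F, 2); gz <- central_diff(F, 3)
  fxx <- central_diff(gx, 1); fyy <- central_diff(gy, 2); fzz <- central_diff(gz, 3)
  fxy <- central_diff(gx, 2); fxz <- central_diff(gx, 3); fyz <- central_diff(gy, 3)

  idx <- which(surf)
  g1 <- gx[idx]; g2 <- gy[idx]; g3 <- gz[idx]
  h11 <- fxx[idx]; h22 <- fyy[idx]; h33 <- fzz[idx]
  h12 <- fxy[idx]; h13 <- fxz[idx]; h23 <- fyz[idx]
  gn2 <- g1^2 + g2^2 + g3^2
  keep <- gn2 > 1e-10
  n_skipped <- sum(!keep)
  idx <- idx[keep]
  g1 <- g1[keep]; g2 <- g2[keep]; g3 <- g3[keep]
  h11 <- h11[keep]; h22 <- h22[keep]; h33 <- h33[keep]
  h12 <- h12[keep]; h13 <- h13[keep]; h23 <- h23[keep]
  gn2 <- gn2[keep]
  gn <- sqrt(gn2)

  gHg <- g1 * (h11 * g1 + h12 * g2 + h13 * g3) +
         g2 * (h12 * g1 + h22 * g2 + h23 * g3) +
         g3 * (h13 * g1 + h23 * g2 + h33 * g3)
  trH <- h11 + h22 + h33
  H <- (gHg - gn2 * trH) / (2 * gn2 * gn)

  a11 <- h22 * h33 - h23^2
  a22 <- h11 * h33 - h13^2
  a33 <- h11 * h22 - h12^2
  a12 <- h23 * h13 - h12 * h33
  a13 <- h12 * h23 - h22 * h13
  a23 <- h12 * h13 - h11 * h23
  K <- (g1^2 * a11 + g2^2 * a22 + g3^2 * a33 +
        2 * (g1 * g2 * a12 + g1 * g3 * a13 + g2 * g3 * a23)) / gn2^2

  disc <- sqrt(pmax(H^2 - K, 0))
  co <- arrayInd(idx, dim(mask))
  out <- tibble(x = co[, 1], y = co[, 2], z = co[, 3],
                k1 = H + disc, k2 = H - disc,
                mean_curv = H, gauss_curv = K)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Assemble the 17-value vascular feature vector
#'
#' Positions 1-11: radius-CDF bins at integer thresholds (zero-padded after
#' the first 1); 12: median radius; 13: mean radius (voxels); 14-17: average
#' and median of mean curvature (1/voxel), then average and median of
#' Gaussian curvature (1/voxel^2). Deterministic for a given mask.
#'
#' @param mask binary 3-D vessel mask.
#' @param presmooth_sd see [surface_curvatures()].
#' @return Named numeric vector of length 17 (names from [feature_names()]).
#' @export
build_feature_vector <- function(mask, presmooth_sd = 1) {
  rad <- extract_radii(mask)
  curv <- surface_curvatures(mask, presmooth_sd)
  v <- setNames(
    c(zero_pad_cdf(rad$cdf_bins),
      median(rad$radii), mean(rad$radii),
      mean(curv$mean_curv), median(curv$mean_curv),
      mean(curv$gauss_curv), median(curv$gauss_curv)),
    feature_names())
  validate_feature_vector(v)
  v
}

#' Validate a 17-value feature vector
#'
#' Structural invariants: length 17, all finite, CDF positions in `[0, 1]`,
#' and the nonzero CDF prefix non-decreasing (padding zeros may follow the
#' first 1).
#'
#' @param values numeric vector of length 17.
#' @return Invisibly `values`; errors if an invariant fails.
#' @export
validate_feature_vector <- function(values) {
  if (length(values) != 17L) stop("feature vector must have 17 values", call. = FALSE)
  if (!all(is.finite(values))) stop("feature vector has non-finite values", call. = FALSE)
  bins <- values[1:11]
  if (any(bins < -1e-9) || any(bins > 1 + 1e-9))
    stop("CDF bins must lie in [0, 1]", call. = FALSE)
  first_one <- which(bins >= 1 - 1e-9)[1]
  prefix <- if (is.na(first_one)) bins else bins[seq_len(first_one)]
  if (any(diff(prefix) < -1e-9))
    stop("CDF bins must be non-decreasing before padding", call. = FALSE)
  invisible(values)
}

#' Feature vector of a phantom or volume via the full image pipeline
#'
#' Preprocesses, segments and featurizes a raw volume; for a
#' `phantom_volume` the intensities are taken from the object.
#'
#' @param x a `phantom_volume` or a 3-D numeric array.
#' @param params a [preprocess_params()] object.
#' @param presmooth_sd see [surface_curvatures()].
#' @return Named numeric vector of length 17.
#' @export
pipeline_features <- function(x, params = preprocess_params(),
                              presmooth_sd = 1) {
  vol <- if (inherits(x, "phantom_volume")) x$intensities else x
  pre <- preprocess_volume(vol, params)
  seg <- segment_vessels(pre$volume, pre$brain_mask)
  build_feature_vector(seg$final_mask, presmooth_sd)
}
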