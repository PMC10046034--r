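# Rasterization of vessel trees into angiographic phantom volumes.

stamp_ball <- function(mask, p, r) {
  d <- dim(mask)
  xs <- max(1L, floor(p[1] - r)):min(d[1], ceiling(p[1] + r))
  ys <- max(1L, floor(p[2] - r)):min(d[2], ceiling(p[2] + r))
  zs <- max(1L, floor(p[3] - r)):min(d[3], ceiling(p[3] + r))
  dx2 <- (xs - p[1])^2
  dy2 <- (ys - p[2])^2
  dz2 <- (zs - p[3])^2
  ball <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
  mask[xs, ys, zs] <- mask[xs, ys, zs] | ball
  mask
}

brain_ellipsoid <- function(shape) {
  ctr <- (shape + 1) / 2
  semi <- 0.45 * shape
  x <- ((seq_len(shape[1]) - ctr[1]) / semi[1])^2
  y <- ((seq_len(shape[2]) - ctr[2]) / semi[2])^2
  z <- ((seq_len(shape[3]) - ctr[3]) / semi[3])^2
  array(outer(outer(x, y, `+`), z, `+`) <= 1, dim = shape)
}

# Smooth multiplicative bias field 1 + amplitude * f with f a random
# second-order polynomial in normalised coordinates scaled to [-1, 1], so
# max(field)/min(field) <= (1 + a)/(1 - a).
make_bias_field <- function(shape, amplitude) {
  if (amplitude == 0) return(array(1, dim = shape))
  if (amplitude < 0 || amplitude >= 1)
    stop("bias_amplitude must be in [0, 1)", call. = FALSE)
  xs <- seq(-1, 1, length.out = shape[1])
  ys <- seq(-1, 1, length.out = shape[2])
  zs <- seq(-1, 1, length.out = shape[3])
  co <- runif(9, -1, 1)
  X <- array(rep(xs, times = shape[2] * shape[3]), dim = shape)
  Y <- array(rep(rep(ys, each = shape[1]), times = shape[3]), dim = shape)
  Z <- array(rep(zs, each = shape[1] * shape[2]), dim = shape)
  f <- co[1] * X + co[2] * Y + co[3] * Z +
       co[4] * X * Y + co[5] * X * Z + co[6] * Y * Z +
       co[7] * (X^2 - 1 / 3) + co[8] * (Y^2 - 1 / 3) + co[9] * (Z^2 - 1 / 3)
  f <- f / max(abs(f))
  1 + amplitude * f
}

#' Rasterize a vessel tree into an angiographic phantom
#'
#' Produces a two-intensity-population volume: vessel voxels (every voxel
#' whose centre lies within the local radius of the centerline) around a
#' bright mean, remaining head tissue around a darker mean, with optional
#' additive Gaussian noise and a smooth multiplicative bias field. With
#' `halo = TRUE` the head is an ellipsoid surrounded by near-zero air, which
#' gives brain-mask extraction something to strip.
#'
#' @param tree a [generate_vessel_tree()] result.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param bias_amplitude relative amplitude of the multiplicative bias field
#'   in `[0, 1)`; the field then lies in `[1 - a, 1 + a]`.
#' @param mu_b,mu_o mean intensity of vessel and of other tissue; must
#'   satisfy `mu_b > mu_o`.
#' @param halo if `TRUE`, voxels outside the head ellipsoid are air (0).
#' @param seed RNG seed for noise and the bias field.
#' @return Object of class `phantom_volume`: list with `intensities`,
#'   `truth_mask`, `centerline` (tibble of points with radii), `bias_field`,
#'   `brain_region`, `voxel_size_mm` and the generation parameters.
#' @export
rasterize_tree <- function(tree, noise_sd = 10, bias_amplitude = 0,
                           mu_b = 200, mu_o = 100, halo = TRUE, seed = 1L) {
  stopifnot(inherits(tree, "vessel_tree"))
  if (mu_b <= mu_o)
    stop("mu_b must exceed mu_o (bright-vessel convention)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  shape <- tree$spec$volume_shape
  truth <- array(FALSE, dim = shape)
  for (b in tree$branches)
    for (i in seq_len(nrow(b$points)))
      truth <- stamp_ball(truth, b$points[i, ], b$radius[i])
  brain <- if (halo) brain_ellipsoid(shape) else array(TRUE, dim = shape)
  local_seed(seed, {
    field <- make_bias_field(shape, bias_amplitude)
    vol <- array(0, dim = shape)
    vol[brain] <- mu_o
    vol[truth] <- mu_b
    vol <- vol * field
    if (noise_sd > 0)
      vol <- vol + array(rnorm(length(vol), sd = noise_sd), dim = shape)
    structure(
      list(intensities = vol,
           truth_mask = truth,
           centerline = tree_points(tree),
           bias_field = field,
           brain_region = brain,
           voxel_size_mm = 1,
           params = list(noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                         mu_b = mu_b, mu_o = mu_o, halo = halo, seed = seed)),
      class = "phantom_volume")
  })
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat("<phantom_volume>", paste(dim(x$intensities), collapse = " x "),
      "voxels;", sum(x$truth_mask), "vessel voxels (",
      round(100 * mean(x$truth_mask), 2), "% )\n")
  invisible(x)
}

#' Standard evaluation phantom
#'
#' Convenience constructor for the reference phantom used by the package's
#' property tests: a 3-root, 3-level tree with root radius 4, intensity
#' separation 100 (vessel 200, tissue 100), and configurable noise and bias.
#'
#' @param shape volume shape (default 128^3).
#' @param noise_sd,bias_amplitude see [rasterize_tree()].
#' @param tortuosity_amplitude bend amplitude of the tree.
#' @param seed RNG seed for both tree and rasterization.
#' @return A `phantom_volume`.
#' @export
standard_phantom <- function(shape = c(128L, 128L, 128L), noise_sd = 15,
                             bias_amplitude = 0.2, tortuosity_amplitude = 1.5,
                             seed = 1L) {
  spec <- vessel_tree_spec(n_root_branches = 3L, branch_levels = 3L,
                           root_radius = 4, radius_decay = 0.8,
                           tortuosity_amplitude = tortuosity_amplitude,
                           volume_shape = shape, seed = seed)
  rasterize_tree(generate_vessel_tree(spec), noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude, seed = seed + 1L)
}
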