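#' Specification of a synthetic vessel tree
#'
#' Describes a branching tubular tree used to build angiographic phantoms:
#' a number of root branches, the number of bifurcation levels, a radius law
#' (root radius in voxels plus a parent-to-child decay factor), and a
#' tortuosity amplitude that bends each branch sinusoidally around its chord.
#'
#' @param n_root_branches number of independent root branches.
#' @param branch_levels number of levels; each non-terminal branch spawns two
#'   children with radius `radius_decay` times the parent's.
#' @param root_radius radius of root branches (voxels, > 0).
#' @param radius_decay child/parent radius ratio in (0, 1].
#' @param tortuosity_amplitude lateral sinusoidal displacement amplitude
#'   (voxels); 0 gives straight branches.
#' @param volume_shape integer 3-vector of volume dimensions (each >= 32).
#' @param seed integer RNG seed; trees are reproducible given the spec.
#' @return A list of class `vessel_tree_spec`.
#' @export
vessel_tree_spec <- function(n_root_branches = 3L,
                             branch_levels = 3L,
                             root_radius = 4,
                             radius_decay = 0.8,
                             tortuosity_amplitude = 1,
                             volume_shape = c(128L, 128L, 128L),
                             seed = 1L) {
  if (root_radius <= 0) stop("root_radius must be > 0", call. = FALSE)
  if (radius_decay <= 0 || radius_decay > 1)
    stop("radius_decay must be in (0, 1]", call. = FALSE)
  if (length(volume_shape) != 3L || any(volume_shape < 32))
    stop("volume_shape must be 3 integers, each >= 32", call. = FALSE)
  if (tortuosity_amplitude < 0)
    stop("tortuosity_amplitude must be >= 0", call. = FALSE)
  if (n_root_branches < 1L || branch_levels < 1L)
    stop("n_root_branches and branch_levels must be >= 1", call. = FALSE)
  structure(
    list(n_root_branches = as.integer(n_root_branches),
         branch_levels = as.integer(branch_levels),
         root_radius = root_radius,
         radius_decay = radius_decay,
         tortuosity_amplitude = tortuosity_amplitude,
         volume_shape = as.integer(volume_shape),
         seed = as.integer(seed)),
    class = "vessel_tree_spec")
}

unit_vector <- function(v) v / sqrt(sum(v^2))

random_unit_vector <- function() {
  v <- rnorm(3)
  while (sum(v^2) < 1e-12) v <- rnorm(3)
  unit_vector(v)
}

perpendicular_basis <- function(dir) {
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit_vector(pracma_cross(dir, ref))
  v <- pracma_cross(dir, u)
  list(u = u, v = v)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotate_about <- function(v, axis, angle) {
  axis <- unit_vector(axis)
  v * cos(angle) + pracma_cross(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

# Points must stay inside an ellipsoid comfortably clear of the volume walls
# (and of the simulated head boundary) by at least the branch radius.
inside_safe_region <- function(p, shape, margin) {
  semi <- 0.45 * shape - margin
  if (any(semi <= 0)) return(FALSE)
  ctr <- (shape + 1) / 2
  sum(((p - ctr) / semi)^2) <= 1
}

grow_branch <- function(start, dir, len, radius, tort, shape, margin) {
  basis <- perpendicular_basis(dir)
  lambda <- max(12, 6 * radius)      # bend wavelength, voxels
  phase <- runif(2, 0, 2 * pi)
  n_pts <- max(2L, ceiling(len))
  s <- seq(0, len, length.out = n_pts)
  pts <- matrix(NA_real_, n_pts, 3)
  cur <- start
  ctr <- (shape + 1) / 2
  for (i in seq_len(n_pts)) {
    off <- tort * (sin(2 * pi * s[i] / lambda + phase[1]) * basis$u +
                   sin(2 * pi * s[i] / (1.7 * lambda) + phase[2]) * basis$v)
    p <- cur + off
    if (!inside_safe_region(p, shape, margin)) {
      # steer the chord back toward the centre and drop the lateral offset
      dir <- unit_vector(ctr - cur)
      basis <- perpendicular_basis(dir)
      p <- cur + dir
    }
    pts[i, ] <- p
    if (i < n_pts) cur <- cur + dir * (s[i + 1] - s[i])
  }
  pts
}

#' Generate a synthetic vessel tree
#'
#' Builds centerline polylines with per-point radii from a
#' [vessel_tree_spec()]. Root branches start near the volume centre with
#' random orientations; each non-terminal branch bifurcates into two children
#' whose radii shrink by the decay factor, so radii are non-increasing from
#' parent to child. Branches are bent by a two-axis sinusoid of the requested
#' amplitude and are steered back toward the centre whenever they approach
#' the safety margin (one maximal radius clear of the head boundary).
#'
#' @param spec a [vessel_tree_spec()].
#' @return An object of class `vessel_tree`: list with `branches` (each a
#'   list with `points` (n x 3 matrix), `radius`, `level`) and `spec`.
#' @export
generate_vessel_tree <- function(spec) {
  stopifnot(inherits(spec, "vessel_tree_spec"))
  shape <- spec$volume_shape
  margin <- spec$root_radius + 2
  if (any(0.45 * shape - margin <= 5))
    stop("vessel radii cannot fit the volume: increase volume_shape or ",
         "decrease root_radius", call. = FALSE)
  local_seed(spec$seed, {
    ctr <- (shape + 1) / 2
    # root length chosen so a straight root from near the centre always fits
    # inside the safety ellipsoid without steering
    base_len <- 0.28 * min(shape)
    branches <- list()
    queue <- list()
    for (b in seq_len(spec$n_root_branches)) {
      start <- ctr + runif(3, -2, 2)
      queue[[length(queue) + 1L]] <-
        list(start = start, dir = random_unit_vector(),
             radius = spec$root_radius, level = 1L)
    }
    while (length(queue) > 0L) {
      node <- queue[[1L]]
      queue <- queue[-1L]
      len <- base_len * 0.7^(node$level - 1L)
      pts <- grow_branch(node$start, node$dir, len, node$radius,
                         spec$tortuosity_amplitude, shape, margin)
      branches[[length(branches) + 1L]] <-
        list(points = pts,
             radius = rep(node$radius, nrow(pts)),
             level = node$level)
      if (node$level < spec$branch_levels) {
        tip <- pts[nrow(pts), ]
        tip_dir <- unit_vector(pts[nrow(pts), ] - pts[max(1, nrow(pts) - 3), ])
        for (child in 1:2) {
          ang <- runif(1, pi / 9, pi / 3.6)   # 20-50 degrees
          axis <- random_unit_vector()
          queue[[length(queue) + 1L]] <-
            list(start = tip, dir = unit_vector(rotate_about(tip_dir, axis, ang)),
                 radius = node$radius * spec$radius_decay,
                 level = node$level + 1L)
        }
      }
    }
    structure(list(branches = branches, spec = spec), class = "vessel_tree")
  })
}

#' Tidy view of a vessel tree
#'
#' @param tree a `vessel_tree`.
#' @return Tibble with one row per centerline point: branch id, level,
#'   x/y/z coordinates and local radius (voxels).
#' @export
tree_points <- function(tree) {
  stopifnot(inherits(tree, "vessel_tree"))
  purrr::map_dfr(seq_along(tree$branches), function(i) {
    b <- tree$branches[[i]]
    tibble(branch = i, level = b$level,
           x = b$points[, 1], y = b$points[, 2], z = b$points[, 3],
           radius = b$radius)
  })
}

#' @export
print.vessel_tree <- function(x, ...) {
  pts <- sum(vapply(x$branches, function(b) nrow(b$points), integer(1)))
  cat("<vessel_tree>", length(x$branches), "branches,", pts,
      "centerline points, root radius", x$spec$root_radius, "voxels\n")
  invisible(x)
}
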