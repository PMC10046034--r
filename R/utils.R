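# Internal helpers shared across modules.

# Run code with a temporary RNG state; restores the caller's stream so that
# seeded generation never perturbs user code.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

assert_volume <- function(x, name = "volume") {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(name, " must be a 3-D array", call. = FALSE)
  invisible(x)
}

assert_finite_volume <- function(x, name = "volume") {
  assert_volume(x, name)
  if (!all(is.finite(x)))
    stop(name, " contains non-finite voxels", call. = FALSE)
  invisible(x)
}

as_binary_array <- function(x, name = "mask") {
  assert_volume(x, name)
  if (is.logical(x)) return(x)
  array(x != 0, dim = dim(x))
}

# Shift a 3-D array by (dx, dy, dz), padding with `fill`. Used for
# neighbourhood operations written as vectorised whole-array expressions.
shift_array <- function(x, dx, dy, dz, fill = 0) {
  d <- dim(x)
  out <- array(fill, dim = d)
  src_x <- max(1, 1 - dx):min(d[1], d[1] - dx)
  src_y <- max(1, 1 - dy):min(d[2], d[2] - dy)
  src_z <- max(1, 1 - dz):min(d[3], d[3] - dz)
  out[src_x + dx, src_y + dy, src_z + dz] <- x[src_x, src_y, src_z]
  out
}

neighbourhood_offsets <- function(connectivity = 26L) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6L) g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1, ]
  g
}

# Maximum over the 26-neighbourhood of each voxel (excluding the voxel).
neighbourhood_max <- function(x) {
  offs <- neighbourhood_offsets(26L)
  out <- array(-Inf, dim = dim(x))
  for (i in seq_len(nrow(offs)))
    out <- pmax(out, shift_array(x, offs$dx[i], offs$dy[i], offs$dz[i],
                                 fill = -Inf))
  out
}

# Separable Gaussian smoothing of a 3-D array via FFT (circular boundary).
# Kernels are truncated at 4 SD and normalised to unit mass.
gaussian_smooth <- function(x, sd = 1) {
  assert_volume(x)
  if (sd <= 0) return(x)
  d <- dim(x)
  kern1d <- function(n) {
    half <- min(floor(n / 2) - 1L, ceiling(4 * sd))
    idx <- c(0:half, if (half >= 1) -(half:1) else integer(0))
    k <- numeric(n)
    k[1 + ((idx + n) %% n)] <- dnorm(idx, sd = sd)
    k / sum(k)
  }
  K <- outer(outer(kern1d(d[1]), kern1d(d[2])), kern1d(d[3]))
  dim(K) <- d
  out <- Re(fft(fft(x) * fft(K), inverse = TRUE)) / length(x)
  array(out, dim = d)
}

label_components <- function(mask, connectivity = 26L) {
  mask <- as_binary_array(mask)
  d <- dim(mask)
  lab <- .cpp_label_components(as.logical(mask), as.integer(d),
                               as.integer(connectivity))
  array(lab, dim = d)
}

largest_component <- function(mask, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) stop("mask is empty", call. = FALSE)
  counts <- tabulate(lab[lab > 0L])
  array(lab == which.max(counts), dim = dim(lab))
}

# Binary dilation/erosion with the 6-neighbourhood cross, iterated.
dilate6 <- function(mask, iterations = 1L) {
  mask <- as_binary_array(mask)
  offs <- neighbourhood_offsets(6L)
  for (it in seq_len(iterations)) {
    acc <- mask
    for (i in seq_len(nrow(offs)))
      acc <- acc | shift_array(mask, offs$dx[i], offs$dy[i], offs$dz[i],
                               fill = FALSE)
    mask <- acc
  }
  mask
}

erode6 <- function(mask, iterations = 1L) {
  mask <- as_binary_array(mask)
  offs <- neighbourhood_offsets(6L)
  for (it in seq_len(iterations)) {
    acc <- mask
    for (i in seq_len(nrow(offs)))
      acc <- acc & shift_array(mask, offs$dx[i], offs$dy[i], offs$dz[i],
                               fill = TRUE)
    mask <- acc
  }
  mask
}

close6 <- function(mask, iterations = 1L) {
  erode6(dilate6(mask, iterations), iterations)
}
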