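# Geometric fixtures built in code: axis-aligned cylinders, spheres, slabs.

# Cylinder along z of geometric radius r: voxels whose (x, y) centre lies
# within r of the axis column. No end caps.
make_cylinder <- function(r, len, shape = c(2 * r + 11, 2 * r + 11, len + 8),
                          center = (shape[1:2] + 1) / 2, z0 = 5) {
  xs <- matrix(seq_len(shape[1]), shape[1], shape[2])
  ys <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  disk <- (xs - center[1])^2 + (ys - center[2])^2 <= r^2
  a <- array(FALSE, shape)
  for (z in z0:(z0 + len - 1)) a[, , z] <- disk
  a
}

make_sphere <- function(R, pad = 6) {
  n <- 2 * R + 2 * pad + 1
  ctr <- (n + 1) / 2
  g <- seq_len(n)
  X <- array(rep(g, times = n * n), c(n, n, n))
  Y <- array(rep(rep(g, each = n), times = n), c(n, n, n))
  Z <- array(rep(g, each = n * n), c(n, n, n))
  (X - ctr)^2 + (Y - ctr)^2 + (Z - ctr)^2 <= R^2
}

make_slab <- function(thickness, shape = c(40, 40, 40), z0 = 15) {
  a <- array(FALSE, shape)
  a[5:(shape[1] - 4), 5:(shape[2] - 4), z0:(z0 + thickness - 1)] <- TRUE
  a
}

# mean gradient magnitude of a volume at given voxels (central differences)
gradient_magnitude <- function(v) {
  sh <- function(dx, dy, dz) {
    d <- dim(v)
    out <- array(0, d)
    sx <- max(1, 1 - dx):min(d[1], d[1] - dx)
    sy <- max(1, 1 - dy):min(d[2], d[2] - dy)
    sz <- max(1, 1 - dz):min(d[3], d[3] - dz)
    out[sx + dx, sy + dy, sz + dz] <- v[sx, sy, sz]
    out
  }
  gx <- (sh(-1, 0, 0) - sh(1, 0, 0)) / 2
  gy <- (sh(0, -1, 0) - sh(0, 1, 0)) / 2
  gz <- (sh(0, 0, -1) - sh(0, 0, 1)) / 2
  sqrt(gx^2 + gy^2 + gz^2)
}

# Table-style demographics used across tests: class-conditional BP of the
# systolic-selected cohort (normal 114.6/78.4, hypertensive 136.6/85.4).
systolic_cohort_bp <- list(
  normotensive = c(sbp_mean = 114.6, sbp_sd = 5.7, dbp_mean = 78.4, dbp_sd = 6.0),
  hypertensive = c(sbp_mean = 136.6, sbp_sd = 7.2, dbp_mean = 85.4, dbp_sd = 6.4))

# A labeled feature cohort with exact per-class sizes, built from BP values
# placed firmly inside class regions. Note SBP < 120 with DBP < 80 forces
# MAP < 93.33 (optimal, excluded from the MAP rule), so three strata are
# needed: A (110/70) is normotensive under the single-component rules,
# C (124/82, MAP ~ 96) is normotensive under the MAP rule (and excluded from
# the systolic one), and B (145/95, MAP ~ 112) is hypertensive under all
# three. Systolic labels: (n_normo, n_hyper); MAP labels: (n_normo, n_hyper).
make_exact_cohort <- function(n_normo, n_hyper, seed = 1,
                              map_stratum = TRUE) {
  withr::with_seed(seed, {
    reps <- c(n_normo, n_hyper, if (map_stratum) n_normo else 0L)
    n <- sum(reps)
    feat <- matrix(rnorm(n * 17), n, 17,
                   dimnames = list(NULL, feature_names()))
    cohort <- tibble::tibble(
      subject_id = sprintf("T%03d", seq_len(n)),
      class = factor(rep(c("normotensive", "hypertensive", "normotensive"),
                         reps),
                     levels = c("normotensive", "hypertensive")),
      source = "original",
      sbp = rep(c(110, 145, 124), reps) + rnorm(n, sd = 2),
      dbp = rep(c(70, 95, 82), reps) + rnorm(n, sd = 1))
    cohort <- label_cohort(cohort)
    dplyr::bind_cols(cohort, tibble::as_tibble(feat))
  })
}
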