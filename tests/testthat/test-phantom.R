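test_that("degenerate single straight branch has one polyline of constant radius", {
  spec <- vessel_tree_spec(n_root_branches = 1, branch_levels = 1,
                           root_radius = 4, tortuosity_amplitude = 0,
                           volume_shape = c(64, 64, 64), seed = 2)
  tree <- generate_vessel_tree(spec)
  expect_length(tree$branches, 1L)
  expect_true(all(tree$branches[[1]]$radius == 4))
  # straight: all points on the chord between the endpoints
  pts <- tree$branches[[1]]$points
  dir <- pts[nrow(pts), ] - pts[1, ]
  dir <- dir / sqrt(sum(dir^2))
  dev <- apply(pts, 1, function(p) {
    d <- p - pts[1, ]
    sqrt(sum((d - sum(d * dir) * dir)^2))
  })
  expect_lt(max(dev), 1e-8)
})

test_that("tree generation is deterministic and radii decay by level", {
  spec <- vessel_tree_spec(n_root_branches = 2, branch_levels = 3,
                           root_radius = 4, radius_decay = 0.7,
                           volume_shape = c(96, 96, 96), seed = 5)
  t1 <- generate_vessel_tree(spec)
  t2 <- generate_vessel_tree(spec)
  expect_identical(t1, t2)
  pts <- tree_points(t1)
  # leaf radii follow root * decay^(levels-1) = 4 * 0.7^2
  expect_equal(unique(pts$radius[pts$level == 3]), 4 * 0.7^2, tolerance = 1e-12)
  # radii non-increasing from parent to child
  by_level <- tapply(pts$radius, pts$level, unique)
  expect_true(all(diff(unlist(by_level)) <= 0))
})

test_that("trees that cannot fit the volume are rejected but valid trees stay inside", {
  expect_error(generate_vessel_tree(
    vessel_tree_spec(root_radius = 14, volume_shape = c(32, 32, 32))),
    "cannot fit")
  for (s in 1:5) {
    spec <- vessel_tree_spec(n_root_branches = 3, branch_levels = 3,
                             root_radius = 4, tortuosity_amplitude = 2,
                             volume_shape = c(96, 96, 96), seed = s)
    pts <- tree_points(generate_vessel_tree(spec))
    margin <- 4  # >= max radius clear of the walls
    expect_true(all(pts$x > margin & pts$x < 96 - margin))
    expect_true(all(pts$y > margin & pts$y < 96 - margin))
    expect_true(all(pts$z > margin & pts$z < 96 - margin))
  }
})

test_that("noiseless rasterization paints vessel voxels at exactly mu_b", {
  spec <- vessel_tree_spec(2, 2, root_radius = 4, volume_shape = c(64, 64, 64),
                           seed = 3)
  ph <- rasterize_tree(generate_vessel_tree(spec), noise_sd = 0,
                       bias_amplitude = 0, halo = FALSE)
  expect_true(all(ph$intensities[ph$truth_mask] == 200))
  expect_true(all(ph$intensities[!ph$truth_mask] == 100))
})

test_that("rasterized straight tubes match the analytic capsule volume", {
  for (r in c(3, 4, 5)) {
    spec <- vessel_tree_spec(1, 1, root_radius = r, tortuosity_amplitude = 0,
                             volume_shape = c(64, 64, 64), seed = 2)
    tree <- generate_vessel_tree(spec)
    L <- sum(sqrt(rowSums(diff(tree$branches[[1]]$points)^2)))
    ph <- rasterize_tree(tree, noise_sd = 0, bias_amplitude = 0, halo = FALSE)
    expected <- pi * r^2 * L + 4 / 3 * pi * r^3  # cylinder + hemispherical caps
    expect_lt(abs(sum(ph$truth_mask) - expected) / expected, 0.05)
  }
})

test_that("bias field amplitude bounds the max/min intensity ratio", {
  spec <- vessel_tree_spec(2, 2, root_radius = 4, volume_shape = c(64, 64, 64),
                           seed = 3)
  tree <- generate_vessel_tree(spec)
  ph <- rasterize_tree(tree, noise_sd = 0, bias_amplitude = 0.2, halo = FALSE,
                       seed = 9)
  expect_lte(max(ph$bias_field) / min(ph$bias_field), 1.5 + 1e-12)
  expect_error(rasterize_tree(tree, mu_b = 90, mu_o = 100), "mu_b")
})

test_that("distance transform of the truth mask matches point radii near the centerline", {
  spec <- vessel_tree_spec(1, 1, root_radius = 4, tortuosity_amplitude = 1,
                           volume_shape = c(64, 64, 64), seed = 7)
  ph <- rasterize_tree(generate_vessel_tree(spec), noise_sd = 0,
                       bias_amplitude = 0, halo = FALSE)
  edt <- distance_map(ph$truth_mask)
  cl <- ph$centerline
  vals <- mapply(function(x, y, z) edt[round(x), round(y), round(z)],
                 cl$x, cl$y, cl$z)
  # interior points (ends are capped) sit within a voxel of the point radius
  interior <- seq(5, nrow(cl) - 5)
  expect_true(all(abs(vals[interior] - cl$radius[interior]) <= 1))
})

test_that("cohorts have requested class sizes and BP moments converge", {
  spec <- cohort_spec(n_per_class = c(68, 48), class_bp_params = systolic_cohort_bp,
                      seed = 11)
  coh <- generate_cohort(spec)
  expect_equal(sum(coh$class == "normotensive"), 68)
  expect_equal(sum(coh$class == "hypertensive"), 48)
  expect_identical(generate_cohort(spec), coh)  # deterministic
  # resting values are the mean of the 4 readings
  expect_equal(coh$sbp, rowMeans(cbind(coh$sbp_1, coh$sbp_2, coh$sbp_3, coh$sbp_4)))
  expect_equal(coh$map_value, compute_map(coh$sbp, coh$dbp))
  # large-sample mean of normotensive SBP approaches the class parameter
  big <- generate_cohort(cohort_spec(n_per_class = c(10000, 2),
                                     class_bp_params = systolic_cohort_bp,
                                     seed = 21))
  expect_lt(abs(mean(big$sbp[big$class == "normotensive"]) - 114.6), 0.5)
})

test_that("zero effect size decouples morphology from class", {
  spec0 <- cohort_spec(n_per_class = c(300, 300), effect_size = 0, seed = 4)
  coh0 <- generate_cohort(spec0)
  r_by_class <- tapply(coh0$root_radius, coh0$class, mean)
  t_by_class <- tapply(coh0$tortuosity, coh0$class, mean)
  expect_lt(abs(diff(r_by_class)), 0.05)
  expect_lt(abs(diff(t_by_class)), 0.05)
  # with coupling, hypertensive radii shift down and tortuosity up
  coh1 <- generate_cohort(cohort_spec(n_per_class = c(300, 300),
                                      effect_size = 0.8, coupling = "class",
                                      seed = 4))
  expect_lt(mean(coh1$root_radius[coh1$class == "hypertensive"]),
            mean(coh1$root_radius[coh1$class == "normotensive"]) - 0.3)
  expect_gt(mean(coh1$tortuosity[coh1$class == "hypertensive"]),
            mean(coh1$tortuosity[coh1$class == "normotensive"]) + 0.1)
})

test_that("volume output attaches rasterized phantoms consistent with the subject", {
  spec <- cohort_spec(n_per_class = c(2, 2), volume_shape = c(48, 48, 48),
                      seed = 6)
  coh <- generate_cohort(spec, output = "volumes")
  expect_length(coh$phantom, 4L)
  expect_s3_class(coh$phantom[[1]], "phantom_volume")
  expect_equal(dim(coh$phantom[[1]]$intensities), c(48, 48, 48))
  expect_true(all(vapply(coh$phantom, function(p) sum(p$truth_mask) > 0,
                         logical(1))))
})
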