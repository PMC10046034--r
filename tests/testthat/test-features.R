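test_that("distance map matches closed forms and a brute-force oracle", {
  single <- array(FALSE, c(9, 9, 9)); single[5, 5, 5] <- TRUE
  expect_equal(distance_map(single)[5, 5, 5], 1)

  r <- 3  # slab of thickness 2r + 1: centre plane is r + 1 from background
  slab <- array(FALSE, c(20, 20, 2 * r + 9))
  slab[, , 5:(5 + 2 * r)] <- TRUE
  edt <- distance_map(slab)
  expect_equal(edt[10, 10, 5 + r], r + 1)

  set.seed(7)
  m <- array(runif(15^3) < 0.4, c(15, 15, 15))
  m[1, , ] <- FALSE
  edt2 <- distance_map(m)
  bg <- which(!m, arr.ind = TRUE)
  fg <- which(m, arr.ind = TRUE)
  sel <- seq(1, nrow(fg), by = 17)
  brute <- vapply(sel, function(i)
    min(sqrt(colSums((t(bg) - fg[i, ])^2))), numeric(1))
  fast <- vapply(sel, function(i) edt2[fg[i, 1], fg[i, 2], fg[i, 3]], numeric(1))
  expect_equal(fast, brute, tolerance = 1e-12)
})

test_that("radius extraction recovers cylinder radii within tolerance", {
  rad <- extract_radii(make_cylinder(4, 60))
  expect_gte(median(rad$radii), 3.5)
  expect_lte(median(rad$radii), 4.5)
  for (r in 2:8) {
    rr <- extract_radii(make_cylinder(r, 40))
    expect_lt(abs(median(rr$radii) - r), max(0.5, 0.15 * r) + 1e-9)
  }
})

test_that("CDF bins form a step function for constant radii and split evenly for two calibres", {
  # full-width slab of thickness 5: every skeleton radius is exactly 3
  slab <- array(FALSE, c(20, 20, 14)); slab[, , 5:9] <- TRUE
  rad <- extract_radii(slab)
  expect_true(all(abs(rad$radii - 3) < 1e-9))
  expect_equal(rad$cdf_bins, c(0, 0, rep(1, 9)))

  # cylinders of radius 2 and 6 with equal skeleton length
  shape <- c(40, 40, 48)
  two <- make_cylinder(2, 40, shape = shape, center = c(10, 10)) |
         make_cylinder(6, 40, shape = shape, center = c(28, 28))
  rad2 <- extract_radii(two)
  expect_lt(abs(rad2$cdf_bins[2] - 0.5), 0.1)
  expect_true(all(diff(rad2$cdf_bins) >= -1e-12))
  expect_equal(rad2$cdf_bins[11], 1)
  expect_equal(sum(rad2$pdf_bins), 1)
})

test_that("zero padding replaces everything after the first saturated bin", {
  expect_equal(zero_pad_cdf(c(0.4, 0.8, 0.9997, 1, 1)),
               c(0.4, 0.8, 0.9997, 1, 0))
  cdf9 <- c(seq(0.2, 0.9, length.out = 8), 1, 1, 1)
  expect_equal(zero_pad_cdf(cdf9)[10:11], c(0, 0))
  cdf11 <- c(seq(0.1, 0.95, length.out = 10), 1)
  expect_equal(zero_pad_cdf(cdf11), cdf11)  # saturates only at the last bin
  expect_error(zero_pad_cdf(c(0.5, 0.4, 1)), "non-decreasing")
})

test_that("surface curvatures match sphere, cylinder and plane oracles", {
  cv <- surface_curvatures(make_sphere(10))
  expect_lt(abs(median(cv$mean_curv) - 1 / 10) / (1 / 10), 0.15)
  expect_lt(abs(median(cv$gauss_curv) - 1 / 100) / (1 / 100), 0.30)
  expect_gt(median(cv$mean_curv), 0)  # convex bright: positive by convention
  expect_true(all(cv$k1 >= cv$k2))

  cyl <- surface_curvatures(make_cylinder(6, 50))
  side <- cyl[cyl$z > 15 & cyl$z < 44, ]  # clear of the open tube ends
  expect_lt(abs(median(side$mean_curv) - 1 / 12) / (1 / 12), 0.15)
  expect_lt(abs(median(side$gauss_curv)), 0.005)

  slab <- surface_curvatures(make_slab(11))
  face <- slab[slab$z == 15 & slab$x > 12 & slab$x < 28 &
               slab$y > 12 & slab$y < 28, ]
  expect_lt(median(abs(face$mean_curv)), 0.01)
  expect_lt(median(abs(face$gauss_curv)), 0.001)
})

test_that("feature vectors are structurally valid and respond to radius shrinkage", {
  fv <- build_feature_vector(make_cylinder(4, 40))
  expect_length(fv, 17L)
  expect_named(fv, feature_names())
  expect_true(all(fv[1:11] >= 0 & fv[1:11] <= 1))
  expect_silent(validate_feature_vector(fv))

  fv2 <- build_feature_vector(make_cylinder(2, 40))
  expect_gt(fv2["cdf_2"], fv["cdf_2"])  # thinner vessels saturate earlier

  # a published-style sample vector passes every structural invariant
  sample_vec <- c(0.429489, 0.636939, 0.779007, 0.863709, 0.922033, 0.961477,
                  0.985828, 0.99689, 0.999308, 0.999915, 1,
                  1.432292, 0.348931, 12.98753, 1.639687, 1.070192, 0.929683)
  expect_silent(validate_feature_vector(sample_vec))
  expect_error(validate_feature_vector(sample_vec[-1]), "17")
  bad <- sample_vec; bad[3] <- 1.2
  expect_error(validate_feature_vector(bad), "\\[0, 1\\]")
})

test_that("tortuosity increases curvature dispersion across seeded phantoms", {
  res <- vapply(1:8, function(s) {
    vapply(c(0.5, 2.5), function(a) {
      sp <- vessel_tree_spec(2, 2, root_radius = 4, tortuosity_amplitude = a,
                             volume_shape = c(64, 64, 64), seed = s)
      ph <- rasterize_tree(generate_vessel_tree(sp), noise_sd = 0,
                           bias_amplitude = 0, halo = FALSE)
      cv <- surface_curvatures(ph$truth_mask)
      c(sd(cv$mean_curv), mean(abs(cv$gauss_curv)))
    }, numeric(2))
  }, matrix(0, 2, 2))
  # res[stat, amplitude, seed]
  expect_gt(mean(res[1, 2, ] - res[1, 1, ]), 0)   # sd of H rises on average
  expect_gt(mean(res[2, 2, ] - res[2, 1, ]), 0)   # mean |K| rises on average
  expect_gte(sum(res[1, 2, ] > res[1, 1, ]), 7)   # and in nearly every seed
})
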