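test_that("intensity model recovers mixture parameters on phantoms", {
  spec <- vessel_tree_spec(2, 2, root_radius = 4, volume_shape = c(64, 64, 64),
                           seed = 3)
  ph <- rasterize_tree(generate_vessel_tree(spec), noise_sd = 10,
                       bias_amplitude = 0, halo = FALSE, seed = 5)
  m <- fit_intensity_model(ph$intensities)
  expect_lt(abs(m$mu_b - 200), 2)
  expect_lt(abs(m$mu_o - 100), 2)
  expect_gt(m$mu_b, m$mu_o)  # ordering convention
  expect_true(all(diff(m$loglik) >= -1e-6 * abs(m$loglik[1])))
  # vessel weight within one percentage point of the true fraction
  expect_lt(abs(m$weight_b - mean(ph$truth_mask)), 0.01)
  expect_error(fit_intensity_model(array(5, c(16, 16, 16))), "degenerate")
})

test_that("intensity model agrees with an independent mixture fit", {
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC  # Mclust looks this up in the caller
  set.seed(2)
  v <- array(c(rnorm(49000, 100, 10), rnorm(1000, 200, 10)), c(50, 50, 20))
  m <- fit_intensity_model(v)
  mc <- mclust::Mclust(as.vector(v)[seq(1, 50000, by = 5)], G = 2,
                       modelNames = "V", verbose = FALSE)
  mu_mc <- sort(mc$parameters$mean)
  expect_lt(abs(m$mu_o - mu_mc[1]), 1.5)
  expect_lt(abs(m$mu_b - mu_mc[2]), 1.5)
})

test_that("initial segmentation decides at the midpoint for a symmetric model", {
  model <- structure(list(mu_b = 200, mu_o = 100, sigma_b = 10, sigma_o = 10,
                          weight_b = 0.5, loglik = 0), class = "intensity_model")
  set.seed(4)
  v <- array(runif(20^3, 50, 250), c(20, 20, 20))
  mask <- initial_segmentation(v, model)
  expect_identical(mask, array(v >= 150, dim = dim(v)))
})

test_that("noiseless phantoms are delineated exactly and within the Gaussian error bound when noisy", {
  spec <- vessel_tree_spec(2, 2, root_radius = 4, volume_shape = c(64, 64, 64),
                           seed = 3)
  tree <- generate_vessel_tree(spec)
  ph0 <- rasterize_tree(tree, noise_sd = 0, bias_amplitude = 0, halo = FALSE)
  m0 <- fit_intensity_model(ph0$intensities)
  expect_identical(initial_segmentation(ph0$intensities, m0), ph0$truth_mask)

  ph <- rasterize_tree(tree, noise_sd = 10, bias_amplitude = 0, halo = FALSE,
                       seed = 6)
  m <- fit_intensity_model(ph$intensities)
  mask <- initial_segmentation(ph$intensities, m)
  err <- mean(mask != ph$truth_mask)
  expect_lt(err, 2 * pnorm(-5) + 1e-4)  # separation 100, SD 10: 5-sigma margin
})

test_that("adaptive refinement uses the local midpoint threshold and recovers thin vessels", {
  # direct substitution: one bright square in a flat slice
  v <- array(100, c(20, 20, 3))
  v[8:12, 8:12, 2] <- 200
  ini <- array(FALSE, dim(v)); ini[8:12, 8:12, 2] <- TRUE
  ref <- adaptive_refine(v, ini)
  rec <- ref$local_thresholds
  expect_equal(rec$threshold[rec$slice == 2], 150)
  expect_identical(ref$mask, ini)  # nothing above T outside the component

  # a dim thin branch missed initially is mostly recovered
  shape <- c(48, 48, 48)
  truth <- make_cylinder(4, 40, shape = shape, z0 = 5)
  thin <- array(FALSE, shape); thin[29:44, 24, 24] <- TRUE
  thin <- vascmap:::dilate6(thin, 1) & !truth
  set.seed(2)
  vol <- array(rnorm(prod(shape), 100, 15), shape)
  vol[truth] <- rnorm(sum(truth), 200, 15)
  vol[thin] <- rnorm(sum(thin), 150, 15)  # partial-volume-dim branch
  m <- fit_intensity_model(vol)
  ini2 <- initial_segmentation(vol, m)
  ref2 <- adaptive_refine(vol, ini2)
  expect_lt(sum(ini2 & thin) / sum(thin), 0.5)
  expect_gte(sum(ref2$mask & thin) / sum(thin), 0.5)
  expect_true(all(ref2$mask[ini2]))  # refined contains initial
  expect_true(all(rec$mu_o < rec$threshold & rec$threshold < rec$mu_b))
})

test_that("seed generation covers the refined mask and flags bright outliers", {
  spec <- vessel_tree_spec(2, 2, root_radius = 4, volume_shape = c(48, 48, 48),
                           seed = 3)
  ph0 <- rasterize_tree(generate_vessel_tree(spec), noise_sd = 0,
                        bias_amplitude = 0, halo = FALSE)
  m0 <- fit_intensity_model(ph0$intensities)
  ini <- initial_segmentation(ph0$intensities, m0)
  seeds <- generate_seeds(ph0$intensities, ini)
  expect_setequal(seeds, which(ph0$truth_mask))  # noiseless: seeds = truth

  empty <- array(FALSE, c(16, 16, 16))
  expect_length(generate_seeds(ph0$intensities[1:16, 1:16, 1:16], empty), 0L)

  # an isolated bright voxel inside a component's window becomes a seed
  v <- array(100, c(24, 24, 3))
  v[10:14, 10:14, 2] <- 200
  v[18, 12, 2] <- 200  # isolated, outside the initial mask but in the window
  ini2 <- array(FALSE, dim(v)); ini2[10:14, 10:14, 2] <- TRUE
  seeds2 <- generate_seeds(v, ini2)
  lin <- 18 + 24 * (12 - 1) + 24 * 24 * (2 - 1)
  expect_true(lin %in% seeds2)
})

test_that("region growing respects connectivity and matches a naive flood fill", {
  # two disjoint bright tubes; seeds only in tube A
  v <- array(100, c(30, 30, 20))
  v[5:8, 5:8, 3:18] <- 200    # tube A
  v[20:23, 20:23, 3:18] <- 200  # tube B
  model <- structure(list(mu_b = 200, mu_o = 100), class = "intensity_model")
  seedA <- 6 + 30 * (6 - 1) + 900 * (10 - 1)    # voxel (6, 6, 10) in tube A
  grown <- region_grow_3d(v, seedA, model)
  expect_true(all(grown[5:8, 5:8, 3:18]))
  expect_false(any(grown[20:23, 20:23, 3:18]))

  # seeds in both tubes recover the full truth
  seedB <- 21 + 30 * (21 - 1) + 900 * (10 - 1)  # voxel (21, 21, 10) in tube B
  grown2 <- region_grow_3d(v, c(seedA, seedB), model)
  expect_identical(grown2, array(v > 150, dim(v)))

  # naive BFS oracle on a random 20^3 volume
  set.seed(8)
  v3 <- array(rnorm(20^3, 100, 40), c(20, 20, 20))
  seeds3 <- which(v3 > 150)[c(1, 5, 9)]
  naive <- naive_flood_fill(v3, seeds3, 150)
  grown3 <- region_grow_3d(v3, seeds3, model, min_component_size = 1L)
  expect_identical(grown3, naive)
})

test_that("overlap metrics follow their definitions", {
  t <- array(FALSE, c(10, 10, 10)); t[2:5, 2:5, 2:5] <- TRUE
  expect_equal(evaluate_segmentation(t, t),
               tibble::tibble(dice = 100, sensitivity = 100, specificity = 100))
  expect_equal(evaluate_segmentation(!t, t)$dice, 0)
  # |T| = 100, |P| = 80, |P n T| = 60
  tr <- array(FALSE, c(10, 10, 10)); tr[1:100] <- TRUE
  pr <- array(FALSE, c(10, 10, 10)); pr[41:120] <- TRUE
  expect_equal(evaluate_segmentation(pr, tr)$dice, 2 * 60 / 180 * 100,
               tolerance = 1e-12)
  expect_error(evaluate_segmentation(pr, array(FALSE, c(10, 10, 10))), "empty")
})

test_that("the segmentation pipeline is monotone and deterministic", {
  spec <- vessel_tree_spec(2, 2, root_radius = 4, volume_shape = c(48, 48, 48),
                           seed = 9)
  ph <- rasterize_tree(generate_vessel_tree(spec), noise_sd = 10,
                       bias_amplitude = 0, halo = FALSE, seed = 2)
  s1 <- segment_vessels(ph$intensities)
  s2 <- segment_vessels(ph$intensities)
  expect_identical(s1$final_mask, s2$final_mask)
  expect_true(all(s1$refined_mask[s1$initial_mask]))
  expect_true(all(which(s1$refined_mask) %in% s1$seeds))
})
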