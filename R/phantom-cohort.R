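# Class-conditional cohort generation: blood pressures plus vascular
# morphology coupled to hypertension severity.

#' Names and order of the 17-value vascular feature vector
#'
#' Positions 1-11 are the radius-CDF bins (zero-padded after the first 1),
#' 12-13 the median and mean vascular radius (voxels), 14-17 the average and
#' median of mean curvature (1/voxel) then of Gaussian curvature (1/voxel^2).
#'
#' @return Character vector of length 17.
#' @export
feature_names <- function() {
  c(paste0("cdf_", 1:11), "radius_median", "radius_mean",
    "mean_curv_avg", "mean_curv_med", "gauss_curv_avg", "gauss_curv_med")
}

#' Specification of a synthetic blood-pressure cohort
#'
#' Class-conditional SBP/DBP normal distributions (defaults pool the
#' demographics of the systolic-, diastolic- and MAP-selected cohorts, so
#' that all three labeling rules yield usable two-class subsets:
#' normotensive 119 +/- 8 over 78.3 +/- 5 mmHg, hypertensive 132 +/- 9 over
#' 85.9 +/- 5.5 mmHg), cohort sizes, and an effect size in `[0, 1]` that
#' couples vascular
#' morphology to hypertension: larger effect shifts radii down and
#' tortuosity up. Coupling is either `"class"` (a fixed shift for the
#' hypertensive class) or `"map"` (proportional to the subject's MAP, so the
#' morphology tracks the continuous pressure burden).
#'
#' @param n_per_class named or unnamed length-2 vector:
#'   c(normotensive, hypertensive) subject counts.
#' @param class_bp_params list with elements `normotensive` and
#'   `hypertensive`, each `c(sbp_mean, sbp_sd, dbp_mean, dbp_sd)` in mmHg.
#' @param effect_size morphology coupling strength in `[0, 1]`.
#' @param coupling `"class"` or `"map"`.
#' @param reading_sd within-subject SD of a single BP reading (mmHg); four
#'   noisy readings per subject are averaged into the resting value.
#' @param root_radius,radius_decay,tortuosity_base baseline morphology of the
#'   vessel trees (voxels / ratio / voxels).
#' @param volume_shape volume dimensions used when volumes are rasterized.
#' @param noise_sd,bias_amplitude rasterization parameters (volume output).
#' @param seed integer RNG seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = c(normotensive = 107L, hypertensive = 54L),
                        class_bp_params = list(
                          normotensive = c(sbp_mean = 119, sbp_sd = 8,
                                           dbp_mean = 78.3, dbp_sd = 5),
                          hypertensive = c(sbp_mean = 132, sbp_sd = 9,
                                           dbp_mean = 85.9, dbp_sd = 5.5)),
                        effect_size = 0.8,
                        coupling = c("class", "map"),
                        reading_sd = 3,
                        root_radius = 4,
                        radius_decay = 0.8,
                        tortuosity_base = 0.8,
                        volume_shape = c(64L, 64L, 64L),
                        noise_sd = 10,
                        bias_amplitude = 0.1,
                        seed = 1L) {
  coupling <- match.arg(coupling)
  if (effect_size < 0 || effect_size > 1)
    stop("effect_size must be in [0, 1]", call. = FALSE)
  for (cls in c("normotensive", "hypertensive")) {
    p <- class_bp_params[[cls]]
    if (length(p) != 4L || any(p[c(2, 4)] <= 0))
      stop("class_bp_params$", cls,
           " must be c(sbp_mean, sbp_sd, dbp_mean, dbp_sd) with SDs > 0",
           call. = FALSE)
  }
  if (length(n_per_class) != 2L || any(n_per_class < 1))
    stop("n_per_class must give two positive counts", call. = FALSE)
  structure(
    list(n_per_class = c(normotensive = as.integer(n_per_class[[1]]),
                         hypertensive = as.integer(n_per_class[[2]])),
         class_bp_params = class_bp_params,
         effect_size = effect_size,
         coupling = coupling,
         reading_sd = reading_sd,
         root_radius = root_radius,
         radius_decay = radius_decay,
         tortuosity_base = tortuosity_base,
         volume_shape = as.integer(volume_shape),
         noise_sd = noise_sd,
         bias_amplitude = bias_amplitude,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

# Severity in [0, 1.5] driving the morphology shift. Class coupling: 0/1.
# MAP coupling: linear ramp above the optimal/normal boundary region.
severity_score <- function(class, map_value, coupling) {
  if (coupling == "class") return(as.numeric(class == "hypertensive"))
  pmin(pmax((map_value - 95) / 8, 0), 1.5)
}

# Emulated 17-value descriptor for a subject's vessel tree, drawn from the
# radius law and tortuosity without rasterizing a volume: skeleton-point
# radii get +/-0.25-voxel discretization jitter, mean curvature per point is
# 1/(2r) inflated by tortuosity, Gaussian curvature is a near-zero spread
# that widens with tortuosity (cylinders have K ~ 0; bends and caps add
# dispersion).
simulate_features <- function(root_radius, radius_decay, tortuosity,
                              n_root = 3L, levels = 3L) {
  radii <- numeric(0)
  for (l in seq_len(levels)) {
    n_branch <- n_root * 2^(l - 1L)
    n_pts <- max(4L, round(40 * 0.7^(l - 1L)))
    r <- root_radius * radius_decay^(l - 1L)
    radii <- c(radii, r + rnorm(n_branch * n_pts, sd = 0.25))
  }
  radii <- pmax(radii, 0.3)
  cdf <- radius_cdf_bins(radii)
  h <- (1 / (2 * radii)) * (1 + 0.8 * tortuosity) + rnorm(length(radii), sd = 0.01)
  k <- rnorm(length(radii), mean = 0.01 * tortuosity / (radii^2 + 1),
             sd = 0.02 / (radii + 1))
  setNames(
    c(zero_pad_cdf(cdf), median(radii), mean(radii),
      mean(h), median(h), mean(k), median(k)),
    feature_names())
}

#' Generate a synthetic labeled cohort
#'
#' Draws class-conditional blood pressures (four noisy readings per subject,
#' averaged into the resting value), labels every subject under the
#' systolic, diastolic and MAP rules, and attaches vascular morphology whose
#' radius/tortuosity parameters are shifted by the effect size (smaller
#' radii, higher tortuosity with increasing hypertension severity).
#'
#' With `output = "features"` each subject carries the 17-value descriptor
#' emulated directly from its morphology parameters; with
#' `output = "volumes"` each subject additionally carries a rasterized
#' `phantom_volume` in a list-column, ready for the image pipeline.
#'
#' @param spec a [cohort_spec()].
#' @param output `"features"` (fast, default) or `"volumes"`.
#' @param rules a [bp_rules()] object used for labeling.
#' @return Tibble with one row per subject: id, generating class, BP
#'   readings, resting `sbp`/`dbp`, `map_value`, the three rule labels,
#'   morphology parameters, `source = "original"`, and feature columns
#'   (see [feature_names()]); plus a `phantom` list-column for volume output.
#' @export
generate_cohort <- function(spec, output = c("features", "volumes"),
                            rules = bp_rules()) {
  stopifnot(inherits(spec, "cohort_spec"))
  output <- match.arg(output)
  local_seed(spec$seed, {
    classes <- rep(c("normotensive", "hypertensive"), spec$n_per_class)
    n <- length(classes)
    reading_cols <- matrix(NA_real_, n, 8)
    sbp <- dbp <- numeric(n)
    for (i in seq_len(n)) {
      p <- spec$class_bp_params[[classes[i]]]
      true_sbp <- rnorm(1, p[1], p[2])
      true_dbp <- rnorm(1, p[3], p[4])
      rs <- true_sbp + rnorm(4, sd = spec$reading_sd)
      rd <- true_dbp + rnorm(4, sd = spec$reading_sd)
      reading_cols[i, ] <- c(rs, rd)
      rest <- resting_bp(rs, rd)
      sbp[i] <- rest["sbp"]
      dbp[i] <- rest["dbp"]
    }
    map_value <- compute_map(sbp, dbp)
    sev <- severity_score(classes, map_value, spec$coupling) * spec$effect_size
    root_radius <- pmax(spec$root_radius * (1 - 0.25 * sev) + rnorm(n, sd = 0.15),
                        0.8)
    tortuosity <- pmax(spec$tortuosity_base * (1 + 1.2 * sev) + rnorm(n, sd = 0.08),
                       0)
    feat <- t(vapply(seq_len(n), function(i)
      simulate_features(root_radius[i], spec$radius_decay, tortuosity[i]),
      numeric(17)))
    cohort <- tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      class = factor(classes, levels = c("normotensive", "hypertensive")),
      source = "original",
      sbp_1 = reading_cols[, 1], sbp_2 = reading_cols[, 2],
      sbp_3 = reading_cols[, 3], sbp_4 = reading_cols[, 4],
      dbp_1 = reading_cols[, 5], dbp_2 = reading_cols[, 6],
      dbp_3 = reading_cols[, 7], dbp_4 = reading_cols[, 8],
      sbp = sbp, dbp = dbp,
      root_radius = root_radius,
      tortuosity = tortuosity)
    cohort <- label_cohort(cohort, rules)
    cohort <- dplyr::bind_cols(cohort, as_tibble(feat))
    if (output == "volumes") {
      vol_seeds <- sample.int(.Machine$integer.max - 1L, n)
      cohort$phantom <- purrr::map(seq_len(n), function(i) {
        ts <- vessel_tree_spec(n_root_branches = 3L, branch_levels = 3L,
                               root_radius = root_radius[i],
                               radius_decay = spec$radius_decay,
                               tortuosity_amplitude = tortuosity[i],
                               volume_shape = spec$volume_shape,
                               seed = vol_seeds[i])
        rasterize_tree(generate_vessel_tree(ts), noise_sd = spec$noise_sd,
                       bias_amplitude = spec$bias_amplitude,
                       seed = vol_seeds[i] %% 100000L + 1L)
      })
    }
    cohort
  })
}
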