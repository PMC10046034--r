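#' Blood-pressure classification rules
#'
#' Threshold set used by the systolic, diastolic and mean-arterial-pressure
#' (MAP) labeling rules. Defaults follow the 2017 ACC/AHA guideline reading
#' used throughout the package: normal requires SBP < 120 mmHg *and*
#' DBP < 80 mmHg; systolic hypertension is SBP > 130 mmHg (strict); diastolic
#' hypertension is DBP > 80 mmHg (strict). The six MAP categories are bounded
#' at 93.33 / 99.00 / 105.67 / 119.00 / 132.33 mmHg, compared after rounding
#' MAP to 2 decimals so the printed interval endpoints partition every value.
#'
#' @param systolic_hypertensive_cut SBP above which a subject is systolic
#'   hypertensive (mmHg, strict inequality).
#' @param diastolic_hypertensive_cut DBP above which a subject is diastolic
#'   hypertensive (mmHg, strict inequality).
#' @param normal_sbp_max,normal_dbp_max upper bounds (strict) for the normal
#'   class under both single-component rules.
#' @param map_boundaries increasing numeric vector of 5 MAP cut points
#'   separating optimal / normal / high-normal / grade 1 / grade 2 / grade 3.
#' @return A list of class `bp_rules`.
#' @export
bp_rules <- function(systolic_hypertensive_cut = 130,
                     diastolic_hypertensive_cut = 80,
                     normal_sbp_max = 120,
                     normal_dbp_max = 80,
                     map_boundaries = c(93.33, 99.00, 105.67, 119.00, 132.33)) {
  if (length(map_boundaries) != 5L || any(diff(map_boundaries) <= 0))
    stop("map_boundaries must be 5 strictly increasing values", call. = FALSE)
  structure(
    list(systolic_hypertensive_cut = systolic_hypertensive_cut,
         diastolic_hypertensive_cut = diastolic_hypertensive_cut,
         normal_sbp_max = normal_sbp_max,
         normal_dbp_max = normal_dbp_max,
         map_boundaries = map_boundaries),
    class = "bp_rules")
}

#' Average repeated blood-pressure readings
#'
#' Four SBP/DBP reading pairs per subject are averaged into the resting value
#' used by every labeling rule.
#'
#' @param sbp,dbp numeric vectors of exactly 4 positive readings (mmHg).
#' @return Named numeric vector with elements `sbp` and `dbp`.
#' @examples
#' resting_bp(c(118, 120, 122, 124), c(78, 80, 79, 81))
#' @export
resting_bp <- function(sbp, dbp) {
  if (length(sbp) != 4L || length(dbp) != 4L)
    stop("exactly 4 SBP and 4 DBP readings are required", call. = FALSE)
  if (any(!is.finite(sbp)) || any(!is.finite(dbp)) ||
      any(sbp <= 0) || any(dbp <= 0))
    stop("readings must be positive and finite", call. = FALSE)
  c(sbp = mean(sbp), dbp = mean(dbp))
}

#' Mean arterial pressure
#'
#' MAP = (1/3) SBP + (2/3) DBP, reported to 2 decimals. The weighting
#' reflects that the heart spends roughly two thirds of the cardiac cycle in
#' diastole.
#'
#' @param sbp,dbp resting systolic / diastolic pressure (mmHg); vectorised.
#' @return MAP in mmHg, rounded to 2 decimals.
#' @examples
#' compute_map(120, 80) # 93.33, the optimal/normal boundary
#' @export
compute_map <- function(sbp, dbp) {
  if (any(sbp < 0) || any(dbp <= 0))
    stop("blood pressures must be positive", call. = FALSE)
  round(sbp / 3 + 2 * dbp / 3, 2)
}

label_factor <- function(x) {
  factor(x, levels = c("normotensive", "hypertensive", "excluded"))
}

#' Systolic and diastolic labeling rules
#'
#' Single-component class assignment: under the systolic rule a subject is
#' hypertensive iff SBP exceeds the systolic cut; under the diastolic rule
#' iff DBP exceeds the diastolic cut. Either rule calls a subject
#' normotensive only when both components are in the normal range
#' (SBP < 120 and DBP < 80 by default); anything else is `excluded` from that
#' sub-experiment (e.g. SBP in the 120-130 band under the systolic rule).
#'
#' @param sbp,dbp resting pressures (mmHg); vectorised.
#' @param rules a [bp_rules()] object.
#' @return factor with levels normotensive / hypertensive / excluded.
#' @export
label_systolic <- function(sbp, dbp, rules = bp_rules()) {
  out <- ifelse(sbp > rules$systolic_hypertensive_cut, "hypertensive",
         ifelse(sbp < rules$normal_sbp_max & dbp < rules$normal_dbp_max,
                "normotensive", "excluded"))
  label_factor(out)
}

#' @rdname label_systolic
#' @export
label_diastolic <- function(sbp, dbp, rules = bp_rules()) {
  out <- ifelse(dbp > rules$diastolic_hypertensive_cut, "hypertensive",
         ifelse(sbp < rules$normal_sbp_max & dbp < rules$normal_dbp_max,
                "normotensive", "excluded"))
  label_factor(out)
}

map_category_levels <- c("optimal", "normal", "high_normal",
                         "grade1", "grade2", "grade3")

#' Six-level MAP categorization and its binary collapse
#'
#' `map_category()` assigns each MAP value to one of six categories:
#' optimal (< 93.33), normal (93.33-99.00), high normal (99.01-105.67),
#' grade 1 (105.68-119.00), grade 2 (119.01-132.33) and grade 3 (>= 132.34)
#' hypertension. MAP is rounded to 2 decimals before comparison, which closes
#' the 0.01-wide gaps between the printed interval endpoints, so every
#' positive MAP receives exactly one category.
#'
#' `collapse_map_category()` folds the six categories into the binary
#' experiment classes: normal becomes normotensive; high normal and all
#' hypertension grades become hypertensive; optimal is excluded (there is no
#' matching category under the single-component rules).
#'
#' @param map_value positive MAP values (mmHg); vectorised.
#' @param category factor returned by `map_category()`.
#' @param rules a [bp_rules()] object.
#' @return `map_category()`: factor with the six category levels;
#'   `collapse_map_category()`: factor normotensive / hypertensive / excluded.
#' @examples
#' map_category(c(92, 96.2, 103.1, 135))
#' collapse_map_category(map_category(96.2))
#' @export
map_category <- function(map_value, rules = bp_rules()) {
  if (any(map_value <= 0)) stop("MAP must be positive", call. = FALSE)
  m <- round(map_value, 2)
  b <- rules$map_boundaries
  eps <- 1e-9
  idx <- 1L +
    (m >= b[1] - eps) + (m > b[2] + eps) + (m > b[3] + eps) +
    (m > b[4] + eps) + (m > b[5] + eps)
  factor(map_category_levels[idx], levels = map_category_levels)
}

#' @rdname map_category
#' @export
collapse_map_category <- function(category) {
  out <- ifelse(category == "optimal", "excluded",
         ifelse(category == "normal", "normotensive", "hypertensive"))
  label_factor(out)
}

#' Label a cohort table under all three rules
#'
#' Adds `map_value`, `label_systolic`, `label_diastolic`, `map_category` and
#' `label_map` columns to a cohort tibble that carries resting `sbp` and
#' `dbp` columns (as produced by [generate_cohort()]).
#'
#' @param cohort data frame with numeric `sbp` and `dbp` columns.
#' @param rules a [bp_rules()] object.
#' @return The input as a tibble with labeling columns appended.
#' @export
label_cohort <- function(cohort, rules = bp_rules()) {
  if (!all(c("sbp", "dbp") %in% names(cohort)))
    stop("cohort must have sbp and dbp columns", call. = FALSE)
  cohort <- as_tibble(cohort)
  cohort$map_value <- compute_map(cohort$sbp, cohort$dbp)
  cohort$label_systolic <- label_systolic(cohort$sbp, cohort$dbp, rules)
  cohort$label_diastolic <- label_diastolic(cohort$sbp, cohort$dbp, rules)
  cohort$map_category <- map_category(cohort$map_value, rules)
  cohort$label_map <- collapse_map_category(cohort$map_category)
  cohort
}
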