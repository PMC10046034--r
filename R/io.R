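# Volume and table I/O: NIfTI for volumes, CSV for cohort/feature tables.

#' Read and write volumes as NIfTI
#'
#' Thin wrappers around RNifti for moving phantom volumes and masks in and
#' out of the standard neuroimaging volume format. Masks are written as
#' 0/1 integer volumes.
#'
#' @param x 3-D numeric or logical array, or a `phantom_volume` (its
#'   intensities are written).
#' @param path file path, conventionally ending `.nii` or `.nii.gz`.
#' @return `write_volume_nifti()` returns `path` invisibly;
#'   `read_volume_nifti()` returns a plain 3-D array.
#' @export
write_volume_nifti <- function(x, path) {
  if (inherits(x, "phantom_volume")) x <- x$intensities
  assert_volume(x)
  if (is.logical(x)) x <- array(as.integer(x), dim = dim(x))
  RNifti::writeNifti(RNifti::asNifti(x), path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

#' Read and write cohort tables as CSV
#'
#' One row per subject. On reading, label columns are restored to the
#' package's factor levels.
#'
#' @param cohort cohort tibble.
#' @param path file path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  for (col in intersect(c("label_systolic", "label_diastolic", "label_map"),
                        names(df)))
    df[[col]] <- label_factor(df[[col]])
  if ("map_category" %in% names(df))
    df$map_category <- factor(df$map_category, levels = map_category_levels)
  if ("class" %in% names(df))
    df$class <- factor(df$class, levels = c("normotensive", "hypertensive"))
  df
}
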