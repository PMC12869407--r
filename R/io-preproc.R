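# NIfTI and covariate-table IO, intensity normalization, missing-value
# exclusion, and leakage-free subject-level splitting.

#' Volume container
#'
#' A 3D intensity array plus voxel spacing (mm). Most package functions
#' accept either a `volume_grid` or a bare 3D array.
#'
#' @param values 3D numeric array, all finite.
#' @param spacing mm triple (default 1 mm isotropic).
#' @return a `volume_grid` object.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(values)) == 3, all(is.finite(values)),
            length(spacing) == 3, all(spacing > 0))
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "volume_grid")
}

vol_values <- function(v) if (inherits(v, "volume_grid")) v$values else v

#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers around RNifti preserving voxel spacing in the header.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a [volume_grid()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  volume_grid(array(as.numeric(img), dim = dim(img)),
              spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @param volume a [volume_grid()] or 3D array (1 mm spacing assumed).
#' @export
write_volume <- function(volume, path) {
  vals <- vol_values(volume)
  sp <- if (inherits(volume, "volume_grid")) volume$spacing else c(1, 1, 1)
  img <- RNifti::asNifti(structure(vals, pixdim = sp), datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a cohort covariate table
#'
#' CSV with a header row; empty fields and `NA` become missing values.
#'
#' @param path CSV path.
#' @return a tibble.
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = c("", "NA", "missing"))
}

#' @rdname read_cohort_csv
#' @param table cohort tibble.
#' @export
write_cohort_csv <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' Percentile min-max intensity normalization with contrast enhancement
#'
#' Two-step normalization: intensities are divided by the volume's given
#' percentile (99th by default) and clipped to `[0, 1]`, then passed through
#' the monotone exponential contrast map
#' `(1 - exp(-contrast * v)) / (1 - exp(-contrast))`, which fixes 0 and 1
#' and reduces to the identity as `contrast -> 0`.
#'
#' @param volume a [volume_grid()] or 3D array.
#' @param percentile reference percentile in `(0, 100]`.
#' @param contrast contrast-enhancement strength; `0` means pure min-max.
#' @return same type as `volume`, values in `[0, 1]`.
#' @export
normalize_intensity <- function(volume, percentile = 99, contrast = 3) {
  vals <- vol_values(volume)
  stopifnot(all(is.finite(vals)), percentile > 0, percentile <= 100)
  p <- stats::quantile(vals, percentile / 100, names = FALSE, type = 7)
  if (p <= 0)
    stop("cannot normalize: the ", percentile,
         "th intensity percentile is not positive")
  v <- pmin(pmax(vals / p, 0), 1)
  out <- if (contrast == 0) v else
    (1 - exp(-contrast * v)) / (1 - exp(-contrast))
  if (inherits(volume, "volume_grid")) volume_grid(out, volume$spacing)
  else out
}

#' Drop scans with missing required covariates
#'
#' Keeps rows whose required covariates are all non-missing; row order is
#' preserved and the removed count is attached as attribute `n_removed`
#' (and reported via `message()`).
#'
#' @param table cohort tibble.
#' @param required character vector of covariate column names; empty means
#'   no filtering.
#' @return filtered tibble with attribute `n_removed`.
#' @export
drop_missing <- function(table, required) {
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols))
    stop("unknown covariate column(s): ", paste(missing_cols, collapse = ", "))
  keep <- rep(TRUE, nrow(table))
  for (cl in required) keep <- keep & !is.na(table[[cl]])
  out <- table[keep, , drop = FALSE]
  n_rm <- sum(!keep)
  if (n_rm > 0)
    message("drop_missing: removed ", n_rm, " scan(s) with missing ",
            paste(required, collapse = "/"))
  attr(out, "n_removed") <- n_rm
  out
}

#' Leakage-free subject-level train/validation/test split
#'
#' Unique subject identifiers are extracted, shuffled with a seeded RNG,
#' and assigned to the three sets by the configured proportions:
#' `floor(f1 * S)` subjects to training, the next `floor(f2 * S)` to
#' validation, and the remainder to test. Every scan of a subject lies in
#' exactly one set.
#'
#' @param table cohort tibble with a `PTID` column.
#' @param fractions length-3 positive vector summing to 1
#'   (default 65/15/20 percent).
#' @param seed integer RNG seed.
#' @return a `dataset_split` with subject-id vectors `train`, `val`,
#'   `test` and scan-index lists `scan_idx$train` etc.
#' @export
split_by_subject <- function(table, fractions = c(0.65, 0.15, 0.20),
                             seed = 1L) {
  stopifnot(length(fractions) == 3, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1")
  subjects <- unique(table$PTID)
  S <- length(subjects)
  if (S < 3) stop("need at least 3 subjects to split, got ", S)
  set.seed(seed)
  shuffled <- sample(subjects)
  n_tr <- floor(fractions[1] * S)
  n_va <- floor(fractions[2] * S)
  train <- shuffled[seq_len(n_tr)]
  val <- shuffled[n_tr + seq_len(n_va)]
  test <- shuffled[(n_tr + n_va + 1):S]
  structure(list(
    train = train, val = val, test = test,
    scan_idx = list(train = which(table$PTID %in% train),
                    val = which(table$PTID %in% val),
                    test = which(table$PTID %in% test)),
    fractions = fractions, seed = as.integer(seed)),
    class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf(
    "<dataset_split> subjects train/val/test = %d/%d/%d; scans = %d/%d/%d\n",
    length(x$train), length(x$val), length(x$test),
    length(x$scan_idx$train), length(x$scan_idx$val),
    length(x$scan_idx$test)))
  invisible(x)
}

#' Write a split manifest as CSV (subject_id, split)
#'
#' @param split a [split_by_subject()] result.
#' @param path CSV path.
#' @export
write_split_csv <- function(split, path) {
  readr::write_csv(tibble::tibble(
    subject_id = c(split$train, split$val, split$test),
    split = rep(c("train", "val", "test"),
                c(length(split$train), length(split$val),
                  length(split$test)))), path)
  invisible(path)
}
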