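# Post-training latent analyses: cohort encoding, latent-covariate
# correlation, single-dimension traversal, and averaged generative
# reconstructions over a grid of the guided latents.

#' Encode a cohort into a latent table
#'
#' Deterministic: posterior means only, batch normalization in evaluation
#' mode. Latent columns are labelled `z0 .. z(d-1)`; all covariate columns
#' of `table` are carried along.
#'
#' @param model trained [build_model()] object.
#' @param volumes list of normalized 3D arrays, parallel to `table` rows.
#' @param table cohort tibble.
#' @return tibble with one row per scan.
#' @export
encode_cohort <- function(model, volumes, table) {
  stopifnot(length(volumes) == nrow(table))
  if (!all(dim(volumes[[1]]) == model$spec$input_shape))
    stop("volume shape ", paste(dim(volumes[[1]]), collapse = "x"),
         " does not match model input ",
         paste(model$spec$input_shape, collapse = "x"))
  enc <- encode_volumes(model, volumes)
  d <- model$spec$latent_dim
  zcols <- stats::setNames(
    lapply(seq_len(d), function(k) enc$mu[k, ]),
    paste0("z", seq_len(d) - 1L))
  dplyr::bind_cols(table, tibble::as_tibble(zcols))
}

#' Correlate latent dimensions with covariates
#'
#' Pairwise-complete Pearson correlation and two-sided p-value for every
#' latent dimension against every named covariate. Cells with fewer than 3
#' complete pairs or zero variance are returned with `NA` and flagged
#' `undefined`.
#'
#' @param latents an [encode_cohort()] table.
#' @param covariates character vector of covariate column names.
#' @return tibble: `latent`, `covariate`, `n`, `r`, `p`, `undefined`.
#' @export
correlate_latents <- function(latents, covariates) {
  zcols <- grep("^z[0-9]+$", names(latents), value = TRUE)
  stopifnot(length(zcols) > 0, all(covariates %in% names(latents)))
  out <- list()
  for (zc in zcols) {
    for (cv in covariates) {
      z <- latents[[zc]]
      y <- latents[[cv]]
      ok <- is.finite(z) & is.finite(y)
      n <- sum(ok)
      if (n < 3 || stats::sd(z[ok]) == 0 || stats::sd(y[ok]) == 0) {
        out[[length(out) + 1L]] <- tibble::tibble(
          latent = zc, covariate = cv, n = n, r = NA_real_, p = NA_real_,
          undefined = TRUE)
      } else {
        ct <- stats::cor.test(z[ok], y[ok])
        out[[length(out) + 1L]] <- tibble::tibble(
          latent = zc, covariate = cv, n = n,
          r = unname(ct$estimate), p = ct$p.value, undefined = FALSE)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Traverse a single latent dimension
#'
#' Decodes latent vectors that are zero everywhere except the traversed
#' dimension; deterministic.
#'
#' @param model trained model.
#' @param dim zero-based latent dimension index (the z0..z(d-1) labels).
#' @param values numeric vector of values to place in that dimension.
#' @param origin length-d base vector for the non-traversed dimensions;
#'   default the zero vector. When the aggregated posterior is off-center
#'   (weak KL), pass the empirical latent means ([latent_means()]) so the
#'   traversal pivots through the data manifold.
#' @return list of 3D arrays, one per value.
#' @export
traverse_latent <- function(model, dim, values, origin = NULL) {
  d <- model$spec$latent_dim
  if (dim < 0 || dim >= d)
    stop("latent index ", dim, " out of range [0, ", d - 1, "]")
  if (is.null(origin)) origin <- numeric(d)
  stopifnot(length(origin) == d)
  z <- matrix(origin, d, length(values))
  z[dim + 1L, ] <- values
  decode_latent(model, z)
}

#' Observed range of a latent dimension
#'
#' Quantile range of an encoded latent column, used as the traversal /
#' reconstruction-grid range.
#'
#' @param latents an [encode_cohort()] table.
#' @param dim zero-based latent index.
#' @param probs quantile pair (default the central 95 percent).
#' @return length-2 numeric.
#' @export
latent_range <- function(latents, dim, probs = c(0.025, 0.975)) {
  stats::quantile(latents[[paste0("z", dim)]], probs, names = FALSE)
}

#' Averaged generative reconstructions over a grid of guided latents
#'
#' For each grid cell, decodes `n_samples` latent codes with the guided
#' dimensions fixed at the cell values and every remaining dimension drawn
#' from a standard normal (capturing inter-subject variability), and stores
#' the voxelwise mean volume. Seeded and reproducible.
#'
#' @param model trained model.
#' @param z0_values,z1_values grid values for the two guided dimensions.
#' @param n_samples samples per cell (>= 1).
#' @param seed RNG seed.
#' @param guided_dims zero-based indices of the two guided dimensions.
#' @param free_sd per-dimension standard deviations for the free (non-guided)
#'   dimensions: either `NULL` (standard normal, the generic prior form) or
#'   a length-d numeric, typically the empirical sds of encoded latents
#'   ([latent_sds()]). With a weak KL weight the aggregated posterior is
#'   much narrower than the prior, and prior-width codes fall outside the
#'   decoder's trained range; empirical widths keep the sampled
#'   inter-subject variability in-distribution.
#' @param free_mean per-dimension centers for the free dimensions: `NULL`
#'   (zero, the prior center) or a length-d numeric, typically the
#'   empirical means of encoded latents ([latent_means()]).
#' @param common_draws reuse the same free-dimension draws in every cell
#'   (common random numbers). The Monte-Carlo error of the cell means then
#'   cancels almost entirely out of between-cell contrasts such as the
#'   voxel-wise GLM slopes; cell means themselves are unbiased either way.
#' @return a `recon_grid`: list with `grid` (tibble `cell`, `z0`, `z1`),
#'   `volumes` (list of mean volumes), `n_samples`, `seed`, `guided_dims`.
#' @export
average_reconstructions <- function(model, z0_values, z1_values,
                                    n_samples = 64L, seed = 1L,
                                    guided_dims = c(0L, 1L),
                                    free_sd = NULL, free_mean = NULL,
                                    common_draws = TRUE) {
  stopifnot(n_samples >= 1, length(guided_dims) == 2)
  d <- model$spec$latent_dim
  stopifnot(all(guided_dims < d))
  if (is.null(free_sd)) free_sd <- rep(1, d)
  if (is.null(free_mean)) free_mean <- numeric(d)
  stopifnot(length(free_sd) == d, all(free_sd >= 0),
            length(free_mean) == d)
  set.seed(seed)
  grid <- expand.grid(z0 = z0_values, z1 = z1_values, KEEP.OUT.ATTRS = FALSE)
  free <- setdiff(seq_len(d), guided_dims + 1L)
  shared <- if (length(free) > 0)
    matrix(stats::rnorm(length(free) * n_samples),
           length(free), n_samples) * free_sd[free] + free_mean[free]
  vols <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    z <- matrix(0, d, n_samples)
    z[guided_dims[1] + 1L, ] <- grid$z0[i]
    z[guided_dims[2] + 1L, ] <- grid$z1[i]
    if (length(free) > 0)
      z[free, ] <- if (common_draws) shared else
        matrix(stats::rnorm(length(free) * n_samples),
               length(free), n_samples) * free_sd[free] + free_mean[free]
    dec <- decode_latent(model, z)
    acc <- dec[[1]]
    if (n_samples > 1) for (s in 2:n_samples) acc <- acc + dec[[s]]
    vols[[i]] <- acc / n_samples
  }
  structure(list(grid = tibble::tibble(cell = seq_len(nrow(grid)),
                                       z0 = grid$z0, z1 = grid$z1),
                 volumes = vols, n_samples = as.integer(n_samples),
                 seed = as.integer(seed),
                 guided_dims = as.integer(guided_dims)),
            class = "recon_grid")
}

#' Empirical per-dimension latent standard deviations and means
#'
#' @param latents an [encode_cohort()] table.
#' @return numeric vector, one value per latent dimension.
#' @export
latent_sds <- function(latents) {
  zcols <- grep("^z[0-9]+$", names(latents), value = TRUE)
  zcols <- zcols[order(as.integer(sub("^z", "", zcols)))]
  vapply(zcols, function(zc) stats::sd(latents[[zc]]), 1)
}

#' @rdname latent_sds
#' @export
latent_means <- function(latents) {
  zcols <- grep("^z[0-9]+$", names(latents), value = TRUE)
  zcols <- zcols[order(as.integer(sub("^z", "", zcols)))]
  vapply(zcols, function(zc) mean(latents[[zc]]), 1)
}

#' Write a reconstruction grid as NIfTI volumes plus a JSON sidecar
#'
#' One NIfTI file per grid cell plus `recon_grid.json` describing grid
#' values, sample count and seed.
#'
#' @param recon a [average_reconstructions()] result.
#' @param dir output directory (created if needed).
#' @export
write_recon_grid <- function(recon, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(recon$volumes))
    write_volume(recon$volumes[[i]],
                 file.path(dir, sprintf("recon_cell%03d.nii.gz", i)))
  jsonlite::write_json(
    list(grid = recon$grid, n_samples = recon$n_samples, seed = recon$seed,
         guided_dims = recon$guided_dims),
    file.path(dir, "recon_grid.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
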