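# Voxel-wise general linear model over averaged reconstructions:
# intensity ~ intercept + main effects of the guided latents + their
# pairwise interaction, fitted independently at every voxel by ordinary
# least squares.

#' Fit the voxel-wise GLM on a reconstruction grid
#'
#' Regresses each voxel's cell-mean intensity on
#' `[1, z0, z1, z0 * z1]` across grid cells (ordinary least squares; one fit
#' per voxel, solved jointly via a single QR decomposition). The grid cell
#' values are treated as fixed regressors. With `standardize = TRUE`
#' (default) z0 and z1 are z-scored over cells before fitting so that
#' coefficient magnitudes are comparable across terms; the scaling used is
#' recorded in the design description.
#'
#' @param recon a [average_reconstructions()] result.
#' @param standardize z-score the latent regressors over grid cells.
#' @return a `glm_maps` list: `intercept`, `beta` (named list of
#'   main-effect maps), `gamma` (named list of interaction maps),
#'   `resid_var`, `design` (term names, design matrix, scaling).
#' @export
fit_voxelwise_glm <- function(recon, standardize = TRUE) {
  stopifnot(inherits(recon, "recon_grid"))
  n <- nrow(recon$grid)
  z0 <- recon$grid$z0
  z1 <- recon$grid$z1
  scaling <- list(z0 = c(mean = 0, sd = 1), z1 = c(mean = 0, sd = 1))
  if (standardize) {
    scaling$z0 <- c(mean = mean(z0), sd = stats::sd(z0))
    scaling$z1 <- c(mean = mean(z1), sd = stats::sd(z1))
    z0 <- (z0 - scaling$z0["mean"]) / scaling$z0["sd"]
    z1 <- (z1 - scaling$z1["mean"]) / scaling$z1["sd"]
  }
  X <- cbind(intercept = 1, z0 = z0, z1 = z1, `z0:z1` = z0 * z1)
  p <- ncol(X)
  if (n <= p)
    stop("need more grid cells (", n, ") than design columns (", p, ")")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  shape <- dim(recon$volumes[[1]])
  Y <- vapply(recon$volumes, as.numeric, numeric(prod(shape)))
  Y <- t(Y)  # cells x voxels
  coefs <- qr.coef(qrX, Y)
  res <- Y - X %*% coefs
  rv <- colSums(res^2) / (n - p)
  as_map <- function(v) array(v, dim = shape)
  structure(list(
    intercept = as_map(coefs["intercept", ]),
    beta = list(z0 = as_map(coefs["z0", ]), z1 = as_map(coefs["z1", ])),
    gamma = list(`z0:z1` = as_map(coefs["z0:z1", ])),
    resid_var = as_map(rv),
    design = list(terms = colnames(X), X = X, n_cells = n,
                  standardized = standardize, scaling = scaling)),
    class = "glm_maps")
}

glm_map_list <- function(maps) {
  c(list(intercept = maps$intercept), maps$beta, maps$gamma,
    list(resid_var = maps$resid_var))
}

#' Summarize coefficient maps inside and outside a region mask
#'
#' @param maps a [fit_voxelwise_glm()] result.
#' @param mask logical array of the map shape.
#' @return tibble: `coefficient`, `region` (inside/outside), `mean`,
#'   `mean_abs`, `sd`, `n_voxels`.
#' @export
roi_summary <- function(maps, mask) {
  stopifnot(inherits(maps, "glm_maps"))
  if (!all(dim(mask) == dim(maps$intercept)))
    stop("mask shape does not match coefficient maps")
  if (!any(mask)) stop("empty mask")
  ml <- glm_map_list(maps)
  out <- list()
  for (nm in names(ml)) {
    for (reg in c("inside", "outside")) {
      v <- if (reg == "inside") ml[[nm]][mask] else ml[[nm]][!mask]
      out[[length(out) + 1L]] <- tibble::tibble(
        coefficient = nm, region = reg, mean = mean(v),
        mean_abs = mean(abs(v)), sd = stats::sd(v), n_voxels = length(v))
    }
  }
  dplyr::bind_rows(out)
}

#' Interaction-to-main-effect ratio
#'
#' Mean `|gamma_01|` divided by the larger of mean `|beta_0|` and mean
#' `|beta_1|`, over "brain" voxels (where the intercept map exceeds
#' `brain_frac` of its maximum). A small ratio quantifies disentanglement
#' of the two guided factors: their joint effect on the reconstructions is
#' additive.
#'
#' @param maps a [fit_voxelwise_glm()] result.
#' @param brain_frac intercept threshold defining brain voxels.
#' @return scalar ratio, or `NA` with attribute `undefined = TRUE` when
#'   both main-effect maps are zero.
#' @export
interaction_ratio <- function(maps, brain_frac = 0.05) {
  stopifnot(inherits(maps, "glm_maps"))
  brain <- maps$intercept > brain_frac * max(maps$intercept)
  if (!any(brain)) brain <- rep(TRUE, length(maps$intercept))
  b0 <- mean(abs(maps$beta$z0[brain]))
  b1 <- mean(abs(maps$beta$z1[brain]))
  if (max(b0, b1) == 0)
    return(structure(NA_real_, undefined = TRUE))
  mean(abs(maps$gamma$`z0:z1`[brain])) / max(b0, b1)
}

#' Write GLM coefficient maps as NIfTI plus a JSON design description
#'
#' @param maps a [fit_voxelwise_glm()] result.
#' @param dir output directory.
#' @export
write_glm_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ml <- glm_map_list(maps)
  for (nm in names(ml))
    write_volume(ml[[nm]], file.path(dir, paste0(
      "glm_", gsub(":", "x", nm), ".nii.gz")))
  jsonlite::write_json(
    list(terms = maps$design$terms, n_cells = maps$design$n_cells,
         standardized = maps$design$standardized),
    file.path(dir, "glm_design.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
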