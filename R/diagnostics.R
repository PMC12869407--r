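# Convergence phase diagrams: latent-mean dispersion over (latent dim, beta)
# grids, and converged guided-correlation maps over (beta, alpha) grids.
# Both train one reduced-budget model per grid cell and label the regimes.

#' Latent-mean dispersion
#'
#' Mean Euclidean distance of latent mean vectors to their centroid:
#' `D_mu = (1/N) sum_i || mu_i - mu_bar ||`. Zero exactly when all rows are
#' identical (posterior collapse to a single point); large values indicate
#' a nearly deterministic autoencoder.
#'
#' @param mu N x d matrix, one latent mean vector per row.
#' @return scalar >= 0.
#' @export
latent_dispersion <- function(mu) {
  mu <- as.matrix(mu)
  if (nrow(mu) == 0) stop("latent_dispersion: empty input")
  centroid <- colMeans(mu)
  mean(sqrt(rowSums(sweep(mu, 2, centroid)^2)))
}

label_dispersion <- function(metric, collapse_frac = 0.05,
                             degenerate_frac = 0.95) {
  ref_med <- stats::median(metric, na.rm = TRUE)
  ref_max <- max(metric, na.rm = TRUE)
  dplyr::case_when(
    is.na(metric) ~ "invalid",
    metric < collapse_frac * ref_med ~ "collapse",
    metric > degenerate_frac * ref_max ~ "degenerate",
    TRUE ~ "stable")
}

label_correlation <- function(abs_r, near_zero = 0.2, saturated = 0.95) {
  dplyr::case_when(
    is.na(abs_r) ~ "invalid",
    abs_r < near_zero ~ "near-zero",
    abs_r > saturated ~ "saturated",
    TRUE ~ "stable")
}

#' Dispersion phase diagram over latent dimensionality and KL weight
#'
#' Trains one unguided model (`alpha = 0` for every term, isolating the KL
#' regularization) per grid cell at a reduced epoch budget, computes the
#' dispersion of validation latent means, and labels each cell: `collapse`
#' when the dispersion falls below `collapse_frac` times the grid median
#' (posterior collapse toward the data mean, the high-beta regime),
#' `degenerate` above `degenerate_frac` times the grid maximum (the
#' near-deterministic-autoencoder regime), else `stable`. Cells whose
#' training fails are labelled `invalid` and the sweep continues.
#'
#' @param volumes,table,split as in [train_vae()].
#' @param latent_dims,betas grid axis values.
#' @param epochs_per_cell shared training budget per cell.
#' @param base_config a [train_config()] supplying everything but
#'   `latent_dim`, `beta`, `epochs`.
#' @param collapse_frac,degenerate_frac regime thresholds (fractions of the
#'   grid median / maximum).
#' @param arch_fn function mapping a latent dimensionality to an
#'   [arch_spec()]; default the desk preset.
#' @return a `phase_diagram` tibble: `latent_dim`, `beta`, `metric`
#'   (`D_mu`), `regime`, `ok`.
#' @export
sweep_dispersion <- function(volumes, table, split, latent_dims, betas,
                             epochs_per_cell = 6L,
                             base_config = train_config(),
                             collapse_frac = 0.05, degenerate_frac = 0.95,
                             arch_fn = NULL) {
  if (is.null(arch_fn))
    arch_fn <- function(d) arch_preset("desk", latent_dim = d)
  grid <- expand.grid(latent_dim = latent_dims, beta = betas,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base_config
    cfg$latent_dim <- as.integer(grid$latent_dim[i])
    cfg$beta <- grid$beta[i]
    cfg$epochs <- as.integer(epochs_per_cell)
    metric <- tryCatch({
      fit <- vae_fit(volumes, table, split, cfg, similarity = NULL,
                     arch = arch_fn(cfg$latent_dim))
      enc <- encode_volumes(fit$model, volumes[split$scan_idx$val])
      latent_dispersion(t(enc$mu))
    }, error = function(e) {
      warning("phase-diagram cell (d=", cfg$latent_dim, ", beta=", cfg$beta,
              ") failed: ", conditionMessage(e))
      NA_real_
    })
    tibble::tibble(latent_dim = cfg$latent_dim, beta = cfg$beta,
                   metric = metric, ok = is.finite(metric))
  })
  out <- dplyr::bind_rows(res)
  out$regime <- label_dispersion(out$metric, collapse_frac, degenerate_frac)
  structure(out, class = c("phase_diagram", class(out)),
            metric_name = "D_mu")
}

#' Correlation phase diagram over KL weight and similarity weight
#'
#' Trains one guided model per cell (a single similarity term tying z0 to
#' `covariate`) at fixed latent dimensionality, and records the converged
#' absolute validation correlation: the mean of |r(z0, covariate)| over the
#' last (up to) 3 epochs, which smooths batch noise. Cells are labelled
#' `near-zero` (similarity regularization too weak to shape the latent),
#' `saturated` (|r| driven to ~1, a non-informative minimum), or `stable`.
#'
#' @inheritParams sweep_dispersion
#' @param alphas similarity-weight axis values.
#' @param latent_dim fixed latent dimensionality (default 8).
#' @param covariate covariate column driving the z0 term.
#' @param metric similarity metric for the term.
#' @param near_zero,saturated regime thresholds on |r|.
#' @param arch_fn as in [sweep_dispersion()].
#' @return a `phase_diagram` tibble: `beta`, `alpha`, `metric` (|r|),
#'   `regime`, `ok`.
#' @export
sweep_correlation <- function(volumes, table, split, betas, alphas,
                              latent_dim = 8L, covariate = "SCORE",
                              epochs_per_cell = 6L,
                              base_config = train_config(),
                              metric = "pearson",
                              near_zero = 0.2, saturated = 0.95,
                              arch_fn = NULL) {
  if (is.null(arch_fn))
    arch_fn <- function(d) arch_preset("desk", latent_dim = d)
  grid <- expand.grid(beta = betas, alpha = alphas, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base_config
    cfg$latent_dim <- as.integer(latent_dim)
    cfg$beta <- grid$beta[i]
    cfg$epochs <- as.integer(epochs_per_cell)
    sim <- similarity_spec(sim_term(0, covariate, grid$alpha[i], metric))
    val <- tryCatch({
      fit <- vae_fit(volumes, table, split, cfg, sim,
                     arch = arch_fn(cfg$latent_dim))
      col <- paste0("val_sim_", covariate)
      tail_r <- abs(utils::tail(fit$history[[col]], 3))
      mean(tail_r)
    }, error = function(e) {
      warning("phase-diagram cell (beta=", cfg$beta, ", alpha=",
              grid$alpha[i], ") failed: ", conditionMessage(e))
      NA_real_
    })
    tibble::tibble(beta = cfg$beta, alpha = grid$alpha[i], metric = val,
                   ok = is.finite(val))
  })
  out <- dplyr::bind_rows(res)
  out$regime <- label_correlation(out$metric, near_zero, saturated)
  structure(out, class = c("phase_diagram", class(out)),
            metric_name = "abs_r")
}

#' Write a phase diagram as long-format CSV
#'
#' @param pd a `phase_diagram` tibble.
#' @param path CSV path.
#' @export
write_phase_diagram_csv <- function(pd, path) {
  readr::write_csv(tibble::as_tibble(pd), path)
  invisible(path)
}
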