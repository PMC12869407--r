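# Downstream evaluation: bootstrap logistic-regression classification of
# AD vs HC from latent representations, per-dimension discriminability, and
# the guided-vs-ablated comparison.

binary_metrics <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  c(accuracy = (tp + tn) / length(truth), sensitivity = sens,
    specificity = spec, balanced_accuracy = (sens + spec) / 2)
}

#' Bootstrap logistic-regression classification of AD vs HC
#'
#' Binarizes the diagnosis (HC = 0, AD = 1; MCI and missing-diagnosis rows
#' are excluded), then repeatedly resamples the training rows with
#' replacement, fits a logistic regression (iteration cap 1000) on the
#' selected feature columns, and evaluates on the fixed test split.
#' Replicates whose resample contains a single class are redrawn (and
#' counted). Reports the mean and sd of accuracy, sensitivity (recall for
#' AD), specificity and balanced accuracy over replicates.
#'
#' @param latents an [encode_cohort()] table (needs `PTID` and `DX`).
#' @param split a [split_by_subject()] result.
#' @param features character vector of feature column names (e.g. `"z0"`,
#'   or all latent columns, or `"SCORE"`).
#' @param replicates bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @param max_iter iteration cap for the logistic fit.
#' @return a `classification_report`: list with `summary` (tibble of
#'   metric, mean, sd), `replicates` (per-replicate tibble), `features`,
#'   `n_train`, `n_test`, `n_redrawn`.
#' @export
classify_bootstrap <- function(latents, split, features,
                               replicates = 100L, seed = 1L,
                               max_iter = 1000L) {
  stopifnot(all(features %in% names(latents)), "DX" %in% names(latents))
  keep <- latents$DX %in% c("HC", "AD")
  dat <- latents[keep, , drop = FALSE]
  if (nrow(dat) == 0) stop("no scans with HC or AD diagnosis")
  y <- as.integer(dat$DX == "AD")
  tr <- which(dat$PTID %in% split$train)
  te <- which(dat$PTID %in% split$test)
  if (length(te) == 0) stop("empty test set after diagnosis filtering")
  if (length(unique(y[tr])) < 2)
    stop("training split does not contain both classes")
  Xtr <- as.matrix(dat[tr, features, drop = FALSE])
  Xte <- as.matrix(dat[te, features, drop = FALSE])
  set.seed(seed)
  reps <- vector("list", replicates)
  n_redrawn <- 0L
  for (r in seq_len(replicates)) {
    repeat {
      idx <- sample(length(tr), replace = TRUE)
      if (length(unique(y[tr][idx])) == 2) break
      n_redrawn <- n_redrawn + 1L
    }
    fit <- suppressWarnings(stats::glm.fit(
      cbind(1, Xtr[idx, , drop = FALSE]), y[tr][idx],
      family = stats::binomial(),
      control = list(maxit = max_iter)))
    eta <- cbind(1, Xte) %*% fit$coefficients
    pred <- as.integer(eta > 0)
    reps[[r]] <- tibble::tibble(replicate = r,
                                !!!as.list(binary_metrics(y[te], pred)))
  }
  reps <- dplyr::bind_rows(reps)
  summ <- tidyr::pivot_longer(reps, -"replicate", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  structure(list(summary = summ, replicates = reps,
                 features = features, n_train = length(tr),
                 n_test = length(te), n_redrawn = n_redrawn),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> features:", paste(x$features, collapse = ", "),
      sprintf("| n_train=%d n_test=%d replicates=%d\n", x$n_train, x$n_test,
              nrow(x$replicates)))
  print(x$summary)
  invisible(x)
}

#' Per-dimension discriminability
#'
#' Runs [classify_bootstrap()] with each single latent dimension as the
#' only feature, and emits boxplot-ready per-class latent distributions.
#'
#' @inheritParams classify_bootstrap
#' @return list with `reports` (one `classification_report` per latent),
#'   `summary` (tibble: dimension x metric), `distributions` (long tibble:
#'   `dimension`, `DX`, `value`).
#' @export
per_dimension_report <- function(latents, split, replicates = 100L,
                                 seed = 1L) {
  zcols <- grep("^z[0-9]+$", names(latents), value = TRUE)
  reports <- stats::setNames(lapply(zcols, function(zc)
    classify_bootstrap(latents, split, zc, replicates, seed)), zcols)
  summ <- dplyr::bind_rows(lapply(zcols, function(zc)
    dplyr::mutate(reports[[zc]]$summary, dimension = zc)))
  keep <- latents$DX %in% c("HC", "AD")
  dist <- tidyr::pivot_longer(
    latents[keep, c("DX", zcols)], -"DX",
    names_to = "dimension", values_to = "value")
  list(reports = reports, summary = summ, distributions = dist)
}

#' Guided-vs-ablated comparison
#'
#' Trains the guided model and its ablation (identical configuration and
#' seed, all similarity weights set to 0 — a plain beta-VAE whose history
#' still logs the similarity values with zero contribution to the total),
#' then compares held-out latent-covariate correlations, the voxel-wise GLM
#' maps on matched reconstruction grids, and z0-only classification.
#'
#' @inheritParams train_vae
#' @param arch as in [vae_fit()].
#' @param replicates bootstrap replicates for the classification reports.
#' @param glm_grid_n grid points per guided axis for the reconstruction
#'   grids.
#' @param n_samples samples per reconstruction-grid cell.
#' @return list with `guided` and `ablated` (each: `fit`, `latents`,
#'   `correlations`, `glm`, `report`) and `comparison` (tibble: one row per
#'   compared metric).
#' @export
run_ablation <- function(volumes, table, split, config, similarity,
                         arch = NULL, replicates = 100L, glm_grid_n = 7L,
                         n_samples = 64L) {
  stopifnot(inherits(similarity, "similarity_spec"))
  ablated_sim <- similarity_spec(lapply(similarity$terms, function(tm) {
    tm$weight <- 0
    tm
  }))
  one_arm <- function(sim) {
    fit <- vae_fit(volumes, table, split, config, sim, arch = arch)
    lat_all <- encode_cohort(fit$model, volumes, table)
    lat <- lat_all[lat_all$PTID %in% split$test, , drop = FALSE]
    covs <- vapply(sim$terms, function(tm) tm$covariate, "")
    cors <- correlate_latents(lat, covs)
    r0 <- latent_range(lat, 0)
    r1 <- latent_range(lat, 1)
    recon <- average_reconstructions(
      fit$model, seq(r0[1], r0[2], length.out = glm_grid_n),
      seq(r1[1], r1[2], length.out = glm_grid_n),
      n_samples = n_samples, seed = config$seed,
      free_sd = latent_sds(lat),
      free_mean = latent_means(lat))
    maps <- fit_voxelwise_glm(recon)
    rep <- classify_bootstrap(lat_all, split, "z0", replicates,
                              seed = config$seed)
    list(fit = fit, latents = lat, correlations = cors, recon = recon,
         glm = maps, report = rep)
  }
  guided <- one_arm(similarity)
  ablated <- one_arm(ablated_sim)
  cor_of <- function(arm, tm) {
    rr <- arm$correlations
    abs(rr$r[rr$latent == paste0("z", tm$latent) &
             rr$covariate == tm$covariate])
  }
  rows <- lapply(similarity$terms, function(tm) tibble::tibble(
    metric = sprintf("abs_r_z%d_%s", tm$latent, tm$covariate),
    guided = cor_of(guided, tm), ablated = cor_of(ablated, tm)))
  ba <- function(arm)
    arm$report$summary$mean[arm$report$summary$metric == "balanced_accuracy"]
  rows <- c(rows, list(
    tibble::tibble(metric = "z0_balanced_accuracy",
                   guided = ba(guided), ablated = ba(ablated)),
    tibble::tibble(metric = "glm_interaction_ratio",
                   guided = as.numeric(interaction_ratio(guided$glm)),
                   ablated = as.numeric(interaction_ratio(ablated$glm)))))
  comparison <- dplyr::mutate(dplyr::bind_rows(rows),
                              difference = .data$guided - .data$ablated)
  list(guided = guided, ablated = ablated, comparison = comparison)
}
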