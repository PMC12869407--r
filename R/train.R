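#' Training configuration
#'
#' Defaults are the desk-scale settings used throughout the package:
#' latent dimension 8, KL weight `beta = 1e-4`, batch size 16, Adam. The
#' full-scale reference configuration uses a learning rate of 2e-5; at desk
#' scale (hundreds of scans, 32^3 voxels) a rate of 1e-3 reaches comparable
#' optimization depth within tens of epochs.
#'
#' @param latent_dim latent dimensionality d.
#' @param learning_rate Adam step size.
#' @param batch_size scans per gradient step. Batch-level correlations are
#'   high-variance below 8; a warning is issued for smaller values.
#' @param epochs training epochs.
#' @param beta KL weight.
#' @param seed integer seed controlling initialization, shuffling and
#'   reparameterization noise.
#' @param optimizer only `"adam"` is available.
#' @param spearman_temperature soft-rank temperature for Spearman terms;
#'   `NULL` means `0.1 * sd` of the latent batch.
#' @param early_stop_patience if non-`NULL`, stop when the validation total
#'   has not improved for this many epochs.
#' @param validate evaluate validation losses each epoch (posterior means,
#'   full-set correlations). Disable to save the per-epoch validation pass
#'   when only end-of-training analyses are needed.
#' @return a `train_config` list.
#' @export
train_config <- function(latent_dim = 8L, learning_rate = 1e-3,
                         batch_size = 16L, epochs = 25L, beta = 1e-4,
                         seed = 1L, optimizer = "adam",
                         spearman_temperature = NULL,
                         early_stop_patience = NULL, validate = TRUE) {
  stopifnot(latent_dim >= 1, learning_rate > 0, batch_size >= 1,
            epochs >= 0, beta >= 0)
  optimizer <- match.arg(optimizer, "adam")
  if (batch_size < 8)
    warning("batch_size < 8: batch-level correlation estimates are ",
            "high-variance; similarity regularization may be noisy")
  structure(list(latent_dim = as.integer(latent_dim),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), beta = beta,
                 seed = as.integer(seed), optimizer = optimizer,
                 spearman_temperature = spearman_temperature,
                 early_stop_patience = early_stop_patience,
                 validate = validate),
            class = "train_config")
}

sim_loss_value <- function(metric, z, y, temperature) {
  if (metric == "pearson") pearson_similarity_loss(z, y)
  else spearman_similarity_loss(z, y, temperature = temperature)
}

sim_loss_grad <- function(metric, z, y, temperature) {
  if (metric == "pearson") pearson_similarity_grad(z, y)
  else spearman_similarity_grad(z, y, temperature = temperature)
}

check_finite_loss <- function(recon, kl, sims, epoch, batch) {
  comp <- c(recon = recon, kl = kl, sims)
  bad <- !is.finite(comp)
  if (any(bad))
    stop("non-finite loss at epoch ", epoch, ", batch ", batch,
         ": first offending component '", names(comp)[which(bad)[1]], "'")
}

#' Train a semi-supervised VAE
#'
#' Seeded, reproducible optimization of the total objective
#' (reconstruction + beta * KL + weighted similarity terms) on the training
#' scans of a subject-level split. Similarity terms are computed per batch
#' on the sampled latent codes; scans with a missing covariate still
#' contribute to reconstruction and KL but are dropped from that batch's
#' correlation. Validation losses are recorded each epoch using posterior
#' means (no sampling) and full-validation-set correlations.
#'
#' @param model a [build_model()] object (its latent dimension must match
#'   `config$latent_dim`).
#' @param volumes list of normalized 3D arrays, parallel to `table` rows.
#' @param table cohort table with `PTID` and every covariate named in
#'   `similarity`.
#' @param split a [split_by_subject()] result.
#' @param config a [train_config()].
#' @param similarity a [similarity_spec()], or `NULL` for a plain beta-VAE.
#' @return list with `model` (trained), `history` (per-epoch tibble),
#'   `skipped_terms` (count of batch similarity terms skipped), `config`,
#'   `similarity`.
#' @export
train_vae <- function(model, volumes, table, split, config,
                      similarity = NULL) {
  stopifnot(inherits(model, "vae_model"), inherits(config, "train_config"))
  stopifnot(length(volumes) == nrow(table))
  d <- model$spec$latent_dim
  stopifnot(d == config$latent_dim)
  terms <- if (is.null(similarity)) list() else similarity$terms
  for (tm in terms) {
    if (tm$latent >= d)
      stop("similarity term targets z", tm$latent, " but latent_dim is ", d)
    if (!tm$covariate %in% names(table))
      stop("similarity covariate '", tm$covariate, "' not in cohort table")
  }
  train_idx <- which(table$PTID %in% split$train)
  val_idx <- which(table$PTID %in% split$val)
  stopifnot(length(train_idx) >= 1)
  vshape <- dim(volumes[[train_idx[1]]])
  if (!all(vshape == model$spec$input_shape))
    stop("volume shape ", paste(vshape, collapse = "x"),
         " does not match the architecture input ",
         paste(model$spec$input_shape, collapse = "x"))
  set.seed(config$seed)
  params <- collect_params(model)
  opt <- adam_init(params)
  step <- 0L
  skipped <- 0L
  hist <- list()
  best_val <- Inf
  stall <- 0L
  sim_names <- vapply(terms, function(t) paste0("sim_", t$covariate), "")
  alphas <- vapply(terms, function(t) t$weight, 1)

  epoch <- 0L
  while (epoch < config$epochs) {
    epoch <- epoch + 1L
    perm <- sample(train_idx)
    starts <- seq(1L, length(perm), by = config$batch_size)
    ep <- c(recon = 0, kl = 0, stats::setNames(rep(0, length(terms)), sim_names),
            total = 0)
    for (bi in seq_along(starts)) {
      idx <- perm[starts[bi]:min(starts[bi] + config$batch_size - 1L,
                                 length(perm))]
      B <- length(idx)
      x <- stack_batch(volumes, idx)
      fw <- vae_forward(model, x, training = TRUE)
      model <- fw$model
      recon <- mse_loss(x, fw$xhat)
      kl <- kl_gaussian(fw$mu, fw$logvar)
      dz_extra <- matrix(0, d, B)
      sims <- stats::setNames(numeric(length(terms)), sim_names)
      for (j in seq_along(terms)) {
        tm <- terms[[j]]
        zrow <- fw$z[tm$latent + 1L, ]
        y <- table[[tm$covariate]][idx]
        v <- sim_loss_value(tm$metric, zrow, y, config$spearman_temperature)
        if (isTRUE(attr(v, "skipped"))) {
          skipped <- skipped + 1L
        } else {
          dz_extra[tm$latent + 1L, ] <- dz_extra[tm$latent + 1L, ] +
            tm$weight * sim_loss_grad(tm$metric, zrow, y,
                                      config$spearman_temperature)
        }
        sims[j] <- as.numeric(v)
      }
      check_finite_loss(recon, kl, sims, epoch, bi)
      lb <- total_loss(recon, kl, sims, config$beta, alphas)
      klg <- kl_gaussian_grad(fw$mu, fw$logvar)
      grads <- vae_backward(model, fw,
                            dxhat = 2 * (fw$xhat - x) / length(x),
                            dz_extra = dz_extra,
                            dmu_extra = config$beta * klg$dmu,
                            dlogvar_extra = config$beta * klg$dlogvar)
      step <- step + 1L
      upd <- adam_step(params, grads, opt, config$learning_rate, step)
      params <- upd$params
      opt <- upd$state
      model <- assign_params(model, params)
      ep <- ep + c(recon = recon, kl = kl, sims, total = lb$total)
    }
    ep <- ep / length(starts)
    do_val <- isTRUE(config$validate) || is.null(config$validate)
    if (do_val) {
      val <- evaluate_vae(model, volumes, table, val_idx, terms, config)
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, !!!as.list(ep),
        !!!stats::setNames(as.list(val), paste0("val_", names(val))))
    } else {
      hist[[epoch]] <- tibble::tibble(epoch = epoch, !!!as.list(ep))
    }
    if (do_val && !is.null(config$early_stop_patience) &&
        length(val_idx) > 0) {
      if (val[["total"]] < best_val - 1e-8) {
        best_val <- val[["total"]]
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$early_stop_patience) break
      }
    }
  }
  list(model = model, history = dplyr::bind_rows(hist),
       skipped_terms = skipped, config = config, similarity = similarity)
}

# Deterministic validation metrics: posterior means (no sampling), batch
# norm in evaluation mode, correlations over the whole validation set.
evaluate_vae <- function(model, volumes, table, idx, terms, config) {
  sim_names <- vapply(terms, function(t) paste0("sim_", t$covariate), "")
  alphas <- vapply(terms, function(t) t$weight, 1)
  if (length(idx) == 0) {
    out <- c(recon = NA_real_, kl = NA_real_,
             stats::setNames(rep(NA_real_, length(terms)), sim_names),
             total = NA_real_)
    return(out)
  }
  enc <- encode_volumes(model, volumes[idx])
  recon <- 0
  bs <- 32L
  for (start in seq(1L, length(idx), by = bs)) {
    sub <- start:min(start + bs - 1L, length(idx))
    xh <- chain_forward(model$decoder, enc$mu[, sub, drop = FALSE],
                        training = FALSE)$out
    x <- stack_batch(volumes, idx[sub])
    recon <- recon + sum((x - xh)^2)
  }
  recon <- recon / (length(idx) * prod(model$spec$input_shape))
  kl <- kl_gaussian(enc$mu, enc$logvar)
  sims <- stats::setNames(numeric(length(terms)), sim_names)
  for (j in seq_along(terms)) {
    tm <- terms[[j]]
    sims[j] <- as.numeric(sim_loss_value(
      tm$metric, enc$mu[tm$latent + 1L, ], table[[tm$covariate]][idx],
      config$spearman_temperature))
  }
  c(recon = recon, kl = kl, sims,
    total = recon + config$beta * kl + sum(alphas * sims))
}

#' Build and train a VAE in one seeded call
#'
#' Seeds the RNG once from `config$seed`, builds the architecture (desk
#' preset by default, at `config$latent_dim`), and trains. Two calls with
#' the same inputs and seed produce identical loss histories and weights.
#'
#' @inheritParams train_vae
#' @param arch an [arch_spec()]; default `arch_preset("desk")` at the
#'   configured latent dimension.
#' @return as [train_vae()].
#' @export
vae_fit <- function(volumes, table, split, config, similarity = NULL,
                    arch = NULL) {
  if (is.null(arch)) arch <- arch_preset("desk", latent_dim = config$latent_dim)
  set.seed(config$seed)
  model <- build_model(arch)
  train_vae(model, volumes, table, split, config, similarity)
}
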