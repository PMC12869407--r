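# The four components of the training objective and their gradients.
#
# Sign conventions: the Gaussian KL is returned as the conventional
# non-negative divergence penalty. (The ELBO literature often prints the
# closed form with the opposite sign and then subtracts it in the total;
# the two flips cancel, so the implemented objective is recon + beta * KL+.)
# Similarity terms return -r so that minimizing the total maximizes the
# targeted correlation.

#' Mean squared reconstruction error
#'
#' Mean of squared voxel differences over all voxels and batch items.
#'
#' @param x,xhat arrays of identical shape.
#' @return scalar.
#' @export
mse_loss <- function(x, xhat) {
  if (!identical(dim(x), dim(xhat)) || length(x) != length(xhat))
    stop("mse_loss: shape mismatch (",
         paste(dim(x), collapse = "x"), " vs ",
         paste(dim(xhat), collapse = "x"), ")")
  mean((x - xhat)^2)
}

#' Gaussian KL divergence penalty
#'
#' Effective non-negative divergence of a diagonal Gaussian posterior
#' `N(mu, diag(sigma^2))` from the standard normal prior:
#' `0.5 * sum_i (mu_i^2 + sigma_i^2 - 1 - log sigma_i^2)`, averaged over the
#' batch when `mu`/`logvar` are d x B matrices. Zero exactly when the
#' posterior equals the prior.
#'
#' @param mu,logvar numeric vectors (one posterior) or d x B matrices.
#' @return scalar >= 0.
#' @export
kl_gaussian <- function(mu, logvar) {
  stopifnot(all(is.finite(mu)), all(is.finite(logvar)),
            length(mu) == length(logvar))
  per <- 0.5 * (mu^2 + exp(logvar) - 1 - logvar)
  if (is.matrix(mu)) mean(colSums(per)) else sum(per)
}

# Gradients of the batch-mean KL penalty.
kl_gaussian_grad <- function(mu, logvar) {
  B <- if (is.matrix(mu)) ncol(mu) else 1L
  list(dmu = mu / B, dlogvar = 0.5 * (exp(logvar) - 1) / B)
}

#' Pearson similarity loss
#'
#' Negative Pearson correlation between a latent batch and a covariate
#' batch. Pairs with a missing covariate (or latent) value are removed
#' before centering, as the batch-correlation procedure prescribes. If fewer
#' than two complete pairs remain, or either vector has zero variance, the
#' term is skipped: the value is 0 with attribute `skipped = TRUE`.
#'
#' @param z,y numeric vectors of equal length.
#' @return scalar in `[-1, 1]` (possibly with attribute `skipped`).
#' @export
pearson_similarity_loss <- function(z, y) {
  stopifnot(length(z) == length(y))
  ok <- is.finite(z) & is.finite(y)
  z <- z[ok]; y <- y[ok]
  if (length(z) < 2L)
    return(structure(0, skipped = TRUE, reason = "fewer than 2 complete pairs"))
  zc <- z - mean(z); yc <- y - mean(y)
  sz <- sqrt(sum(zc^2)); sy <- sqrt(sum(yc^2))
  if (sz == 0 || sy == 0)
    return(structure(0, skipped = TRUE, reason = "zero variance"))
  -sum(zc * yc) / (sz * sy)
}

# Gradient of -r with respect to the full-length z (zeros at missing pairs).
pearson_similarity_grad <- function(z, y) {
  g <- numeric(length(z))
  ok <- is.finite(z) & is.finite(y)
  zs <- z[ok]; ys <- y[ok]
  if (length(zs) < 2L) return(g)
  zc <- zs - mean(zs); yc <- ys - mean(ys)
  sz <- sqrt(sum(zc^2)); sy <- sqrt(sum(yc^2))
  if (sz == 0 || sy == 0) return(g)
  r <- sum(zc * yc) / (sz * sy)
  g[ok] <- -(yc / (sz * sy) - r * zc / sz^2)
  g
}

# Average ranks (ties shared), as used for the covariate side and the
# hard-rank mode.
avg_rank <- function(x) rank(x, ties.method = "average")

# Differentiable soft ranks via pairwise sigmoids:
# sr_i = 1 + sum_{j != i} sigmoid((x_i - x_j) / t).
soft_rank <- function(x, temperature) {
  n <- length(x)
  dmat <- outer(x, x, "-") / temperature
  s <- 1 / (1 + exp(-dmat))
  diag(s) <- 0
  1 + rowSums(s)
}

#' Spearman similarity loss
#'
#' Negative Spearman rank correlation between a latent batch and a covariate
#' batch. In soft mode (the trainable form) the latent values are replaced
#' by differentiable soft ranks (pairwise sigmoids at the given
#' temperature) while the covariate uses exact average ranks; the two rank
#' vectors then enter the Pearson formula. As `temperature -> 0` the value
#' converges to the exact negative Spearman rho. `hard = TRUE` uses exact
#' ranks on both sides.
#'
#' @param z,y numeric vectors of equal length.
#' @param temperature softness of the latent ranks; default `0.1 * sd(z)`
#'   over the complete pairs.
#' @param hard use exact ranks for both vectors (non-differentiable).
#' @return scalar in `[-1, 1]` (possibly with attribute `skipped`).
#' @export
spearman_similarity_loss <- function(z, y, temperature = NULL, hard = FALSE) {
  stopifnot(length(z) == length(y))
  ok <- is.finite(z) & is.finite(y)
  zs <- z[ok]; ys <- y[ok]
  if (length(zs) < 2L)
    return(structure(0, skipped = TRUE, reason = "fewer than 2 complete pairs"))
  if (stats::sd(zs) == 0 || stats::sd(ys) == 0)
    return(structure(0, skipped = TRUE, reason = "zero variance"))
  rz <- if (hard) avg_rank(zs) else {
    if (is.null(temperature)) temperature <- 0.1 * stats::sd(zs)
    soft_rank(zs, temperature)
  }
  pearson_similarity_loss(rz, avg_rank(ys))
}

# Gradient of the soft-rank Spearman loss with respect to the full-length z.
spearman_similarity_grad <- function(z, y, temperature = NULL) {
  g <- numeric(length(z))
  ok <- is.finite(z) & is.finite(y)
  zs <- z[ok]; ys <- y[ok]
  if (length(zs) < 2L || stats::sd(zs) == 0 || stats::sd(ys) == 0) return(g)
  if (is.null(temperature)) temperature <- 0.1 * stats::sd(zs)
  sr <- soft_rank(zs, temperature)
  gp <- pearson_similarity_grad(sr, avg_rank(ys))  # dL/d softrank
  dmat <- outer(zs, zs, "-") / temperature
  sig <- 1 / (1 + exp(-dmat))
  sprime <- sig * (1 - sig) / temperature  # symmetric in (i, j)
  diag(sprime) <- 0
  # dL/dz_i = sum_j S_ij * (gp_i - gp_j)
  g[ok] <- rowSums(sprime) * gp - as.vector(sprime %*% gp)
  g
}

#' Combine loss components into the training objective
#'
#' `total = recon + beta * kl + sum_j alpha_j * similarity_j`, with `kl` the
#' non-negative divergence of [kl_gaussian()]. Minimizing the total drives
#' each targeted correlation toward its maximum.
#'
#' @param recon reconstruction loss.
#' @param kl KL divergence penalty.
#' @param similarity named numeric vector of per-term similarity losses
#'   (each `-r`); may be empty.
#' @param beta KL weight.
#' @param alpha numeric vector of similarity weights, recycled against
#'   `similarity`.
#' @return a `loss_breakdown` list with components `recon`, `kl`,
#'   `similarity`, `total`, `beta`, `alpha`.
#' @export
total_loss <- function(recon, kl, similarity = numeric(0), beta, alpha = numeric(0)) {
  if (length(similarity) > 0) {
    stopifnot(length(alpha) == length(similarity))
    stopifnot(all(alpha >= 0))
  }
  sim <- as.numeric(similarity)
  structure(list(
    recon = recon, kl = kl,
    similarity = stats::setNames(sim, names(similarity)),
    beta = beta, alpha = alpha,
    total = recon + beta * kl + sum(alpha * sim)
  ), class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("total %.6g = recon %.6g + beta(%.3g) * kl %.6g", x$total,
              x$recon, x$beta, x$kl))
  if (length(x$similarity))
    cat(" + sum alpha(", paste(signif(x$alpha, 3), collapse = ","),
        ") * sim(", paste(signif(x$similarity, 3), collapse = ","), ")",
        sep = "")
  cat("\n")
  invisible(x)
}

#' Similarity regularization specification
#'
#' A list of terms, each tying one latent dimension to one covariate with a
#' weight and a metric. Latent indices are zero-based, matching the
#' z0..z(d-1) labelling.
#'
#' @param ... term lists created by [sim_term()].
#' @return a `similarity_spec` object.
#' @export
similarity_spec <- function(...) {
  terms <- list(...)
  if (length(terms) == 1 && is.list(terms[[1]]) && is.null(terms[[1]]$latent))
    terms <- terms[[1]]
  idx <- vapply(terms, function(t) t$latent, 1)
  stopifnot(!anyDuplicated(idx), all(idx >= 0))
  stopifnot(all(vapply(terms, function(t) t$weight, 1) >= 0))
  stopifnot(all(vapply(terms, function(t) t$metric, "") %in%
                  c("pearson", "spearman")))
  structure(list(terms = terms), class = "similarity_spec")
}

#' @rdname similarity_spec
#' @param latent zero-based latent dimension index.
#' @param covariate covariate column name (e.g. `"SCORE"`, `"AGE"`).
#' @param weight regularization weight `alpha_j >= 0`.
#' @param metric `"pearson"` or `"spearman"`.
#' @export
sim_term <- function(latent, covariate, weight, metric = "pearson") {
  list(latent = as.integer(latent), covariate = covariate,
       weight = weight, metric = match.arg(metric, c("pearson", "spearman")))
}
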