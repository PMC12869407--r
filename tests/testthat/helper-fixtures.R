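# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small cohort for fast unit tests (not the study conditions).
tiny_cohort <- function() {
  cached("tiny_cohort", {
    coh <- generate_cohort(phantom_config(n_subjects = 12L,
                                          scans_per_subject = 2L,
                                          seed = 101L))
    coh$norm <- lapply(coh$volumes, normalize_intensity)
    coh
  })
}

# A small architecture that trains in seconds (16^3 input).
tiny_arch <- function(latent_dim = 4L) {
  arch_spec(c(16L, 16L, 16L),
            enc_kernels = c(3, 3), enc_channels = c(4, 8),
            enc_strides = c(2, 2), enc_pads = c(1, 1),
            enc_fc = 16L, latent_dim = latent_dim,
            dec_start_ch = 8L, dec_kernels = c(4, 4),
            dec_channels = c(4, 4), dec_strides = c(2, 2),
            dec_pads = c(1, 1), dec_outpads = c(0, 0), final_kernel = 1L)
}

# Independent Pearson/Spearman references via stats::cor.
ref_pearson <- function(z, y) stats::cor(z, y)
ref_spearman <- function(z, y) stats::cor(z, y, method = "spearman")

# Reference conv3d via the package's im2col path (independent of the direct
# C++ kernels used by the layers).
ref_conv3d <- function(x, W, b, k, s, p) {
  cols <- simvae:::.im2col3d(x, dim(x), k, s, p)
  out <- crossprod(W, cols) + b
  osp <- floor((dim(x)[2:4] + 2 * p - k) / s) + 1
  array(out, dim = c(ncol(W), osp, dim(x)[5]))
}
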