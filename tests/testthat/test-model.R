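# Architecture shape arithmetic, convolution kernels vs oracles,
# reparameterization, gradient flow.

test_that("full-scale preset flattens to 9216 features (256 x 3x4x3)", {
  sp <- arch_preset("full")
  expect_equal(sp$flatten, 9216L)
  expect_equal(sp$enc_channels[4] * prod(sp$enc_shapes[[4]]), 9216L)
  expect_equal(sp$enc_shapes[[4]], c(3L, 4L, 3L))
})

test_that("desk preset closes its shape arithmetic at 32^3", {
  sp <- arch_preset("desk")
  expect_equal(sp$input_shape, c(32L, 32L, 32L))
  expect_equal(sp$dec_shapes[[length(sp$dec_shapes)]], c(32L, 32L, 32L))
  # independent convolution shape arithmetic
  out <- c(32L, 32L, 32L)
  for (i in seq_along(sp$enc_kernels))
    out <- floor((out + 2 * sp$enc_pads[i] - sp$enc_kernels[i]) /
                   sp$enc_strides[i]) + 1L
  expect_equal(prod(out) * sp$enc_channels[4], sp$flatten)
})

test_that("invalid shape arithmetic fails naming the offending layer", {
  expect_error(
    arch_spec(c(8L, 8L, 8L), enc_kernels = 11, enc_channels = 4,
              enc_strides = 4, enc_pads = 0, enc_fc = 8L, latent_dim = 2L,
              dec_start_ch = 4L, dec_kernels = 4, dec_channels = 4,
              dec_strides = 2, dec_pads = 1, dec_outpads = 0),
    "encoder conv layer 1")
  expect_error(
    arch_spec(c(16L, 16L, 16L), enc_kernels = c(3, 3), enc_channels = c(4, 4),
              enc_strides = c(2, 2), enc_pads = c(1, 1), enc_fc = 8L,
              latent_dim = 2L, dec_start_ch = 4L, dec_kernels = 4,
              dec_channels = 1, dec_strides = 2, dec_pads = 1,
              dec_outpads = 0),
    "decoder output shape")
})

test_that("latent_dim = 1 yields scalar posteriors per scan", {
  m <- build_model(tiny_arch(latent_dim = 1L), seed = 1)
  x <- array(runif(16^3 * 3), c(1, 16, 16, 16, 3))
  enc <- encode_volumes(m, lapply(1:3, function(i) x[1, , , , i]))
  expect_equal(dim(enc$mu), c(1L, 3L))
  expect_equal(dim(enc$logvar), c(1L, 3L))
})

test_that("direct conv kernels agree with the im2col route and a naive loop", {
  set.seed(11)
  x <- array(rnorm(3 * 9 * 8 * 7 * 2), c(3, 9, 8, 7, 2))
  l <- simvae:::layer_conv3d(3L, 5L, 3L, 2L, 1L, c(9L, 8L, 7L))
  fw <- simvae:::layer_forward(l, x)
  expect_equal(fw$out, ref_conv3d(x, l$params$W, l$params$b, 3, 2, 1),
               tolerance = 1e-12)
  # naive R triple loop on a tiny case
  x1 <- array(rnorm(1 * 5 * 5 * 5), c(1, 5, 5, 5, 1))
  l1 <- simvae:::layer_conv3d(1L, 2L, 3L, 1L, 0L, c(5L, 5L, 5L))
  out1 <- simvae:::layer_forward(l1, x1)$out
  for (co in 1:2) for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    patch <- x1[1, i:(i + 2), j:(j + 2), k:(k + 2), 1]
    w <- array(l1$params$W[, co], c(1, 3, 3, 3))
    expect_equal(out1[co, i, j, k, 1],
                 sum(patch * w[1, , , ]) + l1$params$b[co],
                 tolerance = 1e-12)
  }
})

test_that("transposed conv is the adjoint of conv with the same geometry", {
  # <conv(x), y> == <x, convt(y)> when convt uses the same weights
  set.seed(12)
  k <- 3L; s <- 2L; p <- 1L
  lc <- simvae:::layer_conv3d(2L, 4L, k, s, p, c(8L, 8L, 8L))
  x <- array(rnorm(2 * 8^3 * 2), c(2, 8, 8, 8, 2))
  cy <- simvae:::layer_forward(lc, x)$out
  y <- array(rnorm(length(cy)), dim = dim(cy))
  lt <- simvae:::layer_convt3d(4L, 2L, k, s, p, 1L, c(4L, 4L, 4L))
  # with matching layouts the same weight matrix realizes the adjoint
  lt$params$W <- lc$params$W
  lt$params$b <- numeric(2)
  ty <- simvae:::layer_forward(lt, y)$out
  lhs <- sum((cy - lc$params$b) * y)  # bias recycles along the channel axis
  expect_equal(lhs, sum(x * ty), tolerance = 1e-8)
})

test_that("reparameterize is deterministic given eps and Monte-Carlo sane", {
  mu <- c(0.5, -1)
  lv <- c(0, log(4))
  expect_equal(reparameterize(mu, lv, eps = c(0, 0)), mu)
  expect_equal(reparameterize(mu, lv, eps = c(1, 1)), mu + c(1, 2))
  # sigma -> 0 limit returns mu
  expect_equal(reparameterize(mu, c(-100, -100), eps = rnorm(2)), mu,
               tolerance = 1e-6)
  set.seed(13)
  z <- reparameterize(rep(0, 1e5), rep(0, 1e5))
  expect_lt(abs(mean(z)), 0.02)
  expect_lt(abs(sd(z) - 1), 0.02)
  set.seed(99)
  z1 <- reparameterize(mu, lv)
  set.seed(99)
  z2 <- reparameterize(mu, lv)
  expect_identical(z1, z2)
})

test_that("similarity gradient reaches encoder parameters through z", {
  set.seed(14)
  m <- build_model(tiny_arch(), seed = 3)
  B <- 6
  x <- array(runif(16^3 * B), c(1, 16, 16, 16, B))
  y <- rnorm(B)
  fw <- simvae:::vae_forward(m, x, training = TRUE)
  dz <- matrix(0, 4, B)
  dz[1, ] <- 0.5 * simvae:::pearson_similarity_grad(fw$z[1, ], y)
  grads <- simvae:::vae_backward(m, fw, dxhat = array(0, dim = dim(fw$xhat)),
                                 dz_extra = dz)
  enc_w <- grads[["enc01.W"]]
  expect_true(all(is.finite(enc_w)))
  expect_gt(max(abs(enc_w)), 0)
  expect_gt(max(abs(grads[["mu.W"]])), 0)
})

test_that("model forward output has the input shape", {
  m <- build_model(tiny_arch(), seed = 5)
  x <- array(runif(16^3 * 2), c(1, 16, 16, 16, 2))
  fw <- simvae:::vae_forward(m, x)
  expect_equal(dim(fw$xhat), c(1L, 16L, 16L, 16L, 2L))
  expect_equal(dim(fw$mu), c(4L, 2L))
})
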