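# Loss components: closed-form examples, oracle equivalence, invariants.

test_that("mse_loss matches hand values and a brute-force oracle", {
  expect_equal(mse_loss(array(1, c(2, 2)), array(1, c(2, 2))), 0)
  expect_equal(mse_loss(c(0, 1), c(0, 0)), 0.5)
  set.seed(1)
  for (i in 1:20) {
    x <- array(rnorm(24), c(2, 3, 4))
    y <- array(rnorm(24), c(2, 3, 4))
    expect_equal(mse_loss(x, y), sum((x - y)^2) / length(x),
                 tolerance = 1e-12)
  }
  expect_error(mse_loss(array(0, c(2, 2)), array(0, c(4, 1))),
               "shape mismatch")
})

test_that("kl_gaussian matches the closed form and is zero at the prior", {
  expect_equal(kl_gaussian(0, 0), 0)
  expect_equal(kl_gaussian(1, 0), 0.5)
  set.seed(2)
  for (i in 1:20) {
    mu <- rnorm(5)
    lv <- rnorm(5, 0, 0.7)
    expect_equal(kl_gaussian(mu, lv),
                 0.5 * sum(mu^2 + exp(lv) - 1 - lv), tolerance = 1e-12)
  }
  # matrix input averages per-item sums over the batch
  mu <- matrix(rnorm(8), 2, 4)
  lv <- matrix(rnorm(8), 2, 4)
  per_item <- vapply(1:4, function(b) kl_gaussian(mu[, b], lv[, b]), 1)
  expect_equal(kl_gaussian(mu, lv), mean(per_item), tolerance = 1e-12)
})

test_that("kl_gaussian agrees with numerical quadrature", {
  kl_quad <- function(mu, sigma) {
    # KL(N(mu, sigma^2) || N(0,1)) by numeric integration per dimension
    sum(vapply(seq_along(mu), function(i) {
      f <- function(x) {
        q <- stats::dnorm(x, mu[i], sigma[i])
        lq <- stats::dnorm(x, mu[i], sigma[i], log = TRUE)
        lp <- stats::dnorm(x, 0, 1, log = TRUE)
        q * (lq - lp)
      }
      stats::integrate(f, mu[i] - 10 * sigma[i] - 10,
                       mu[i] + 10 * sigma[i] + 10,
                       rel.tol = 1e-10)$value
    }, 1))
  }
  set.seed(3)
  for (i in 1:25) {
    mu <- rnorm(3)
    lv <- rnorm(3, 0, 0.8)
    expect_equal(kl_gaussian(mu, lv), kl_quad(mu, exp(lv / 2)),
                 tolerance = 1e-4)
  }
})

test_that("kl_gaussian is non-negative, zero only at the prior", {
  set.seed(4)
  vals <- replicate(1000, kl_gaussian(rnorm(4, 0, 2), rnorm(4, 0, 1.5)))
  expect_true(all(vals >= 0))
  expect_true(all(vals[abs(vals) < 1e-12] == 0))  # no negative rounding
  expect_gt(min(vals), 0)  # random posteriors never hit the prior exactly
})

test_that("pearson similarity loss equals -r and matches stats::cor", {
  z <- c(0.3, 1.2, -0.5, 2.0)
  expect_equal(pearson_similarity_loss(z, 2 * z + 1), -1)
  expect_equal(pearson_similarity_loss(z, -z), 1)
  set.seed(5)
  for (i in 1:30) {
    z <- rnorm(64)
    y <- rnorm(64)
    expect_equal(as.numeric(pearson_similarity_loss(z, y)),
                 -ref_pearson(z, y), tolerance = 1e-6)
  }
})

test_that("pearson loss drops missing pairs and skips degenerate batches", {
  z <- c(1, 2, 3, 4)
  y <- c(2, NA, 6, 8)
  expect_equal(as.numeric(pearson_similarity_loss(z, y)),
               -ref_pearson(z[-2], y[-2]))
  v <- pearson_similarity_loss(c(1, 2), c(NA, NA))
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "skipped"))
  v2 <- pearson_similarity_loss(c(1, 1, 1), c(1, 2, 3))
  expect_true(attr(v2, "skipped"))
})

test_that("pearson loss is scale-equivariant and antisymmetric in y", {
  set.seed(6)
  for (i in 1:10) {
    z <- rnorm(16)
    y <- rnorm(16)
    expect_equal(as.numeric(pearson_similarity_loss(3.7 * z + 2, y)),
                 as.numeric(pearson_similarity_loss(z, y)), tolerance = 1e-6)
    expect_equal(as.numeric(pearson_similarity_loss(z, -y)),
                 -as.numeric(pearson_similarity_loss(z, y)),
                 tolerance = 1e-12)
  }
})

test_that("pearson gradient matches finite differences", {
  set.seed(7)
  z <- rnorm(12)
  y <- rnorm(12)
  y[5] <- NA
  g <- simvae:::pearson_similarity_grad(z, y)
  h <- 1e-6
  for (i in seq_along(z)) {
    zp <- z; zp[i] <- zp[i] + h
    zm <- z; zm[i] <- zm[i] - h
    num <- (as.numeric(pearson_similarity_loss(zp, y)) -
            as.numeric(pearson_similarity_loss(zm, y))) / (2 * h)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
  expect_equal(g[5], 0)  # missing pair contributes no gradient
})

test_that("spearman loss: hard ranks match stats::cor, soft ranks converge", {
  z <- c(0.1, -1, 2, 0.5, 1.4, -0.2)
  expect_equal(as.numeric(spearman_similarity_loss(z, z^3, hard = TRUE)), -1)
  expect_equal(
    as.numeric(spearman_similarity_loss(z, -z, hard = TRUE)), 1)
  set.seed(8)
  for (i in 1:20) {
    z <- rnorm(64)
    y <- rnorm(64)
    expect_equal(as.numeric(spearman_similarity_loss(z, y, hard = TRUE)),
                 -ref_spearman(z, y), tolerance = 1e-6)
  }
  # temperature -> 0 limit approaches the exact rank correlation
  z <- rnorm(32)
  y <- rnorm(32)
  expect_equal(
    as.numeric(spearman_similarity_loss(z, y, temperature = 1e-6)),
    -ref_spearman(z, y), tolerance = 1e-3)
})

test_that("soft-rank spearman gradient matches finite differences", {
  set.seed(9)
  z <- rnorm(10)
  y <- rnorm(10)
  g <- simvae:::spearman_similarity_grad(z, y, temperature = 0.4)
  h <- 1e-6
  for (i in seq_along(z)) {
    zp <- z; zp[i] <- zp[i] + h
    zm <- z; zm[i] <- zm[i] - h
    num <- (as.numeric(spearman_similarity_loss(zp, y, temperature = 0.4)) -
            as.numeric(spearman_similarity_loss(zm, y, temperature = 0.4))) /
           (2 * h)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("total_loss composes the weighted objective", {
  lb <- total_loss(0.2, 1.0, c(score = -0.8), beta = 1e-4, alpha = 2e-4)
  expect_equal(lb$total, 0.2 + 1e-4 - 1.6e-4, tolerance = 1e-12)
  expect_equal(total_loss(0.37, 5, beta = 0)$total, 0.37)
  expect_equal(total_loss(0, 0, c(a = -1, b = 0.5), beta = 1,
                          alpha = c(0, 0))$total, 0)
})

test_that("similarity_spec validates its terms", {
  s <- similarity_spec(sim_term(0, "SCORE", 2e-4),
                       sim_term(1, "AGE", 2e-4, metric = "spearman"))
  expect_length(s$terms, 2)
  expect_error(similarity_spec(sim_term(0, "A", 1), sim_term(0, "B", 1)))
  expect_error(similarity_spec(sim_term(0, "A", -1)))
})
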