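# Cohort encoding, latent-covariate correlation, traversal, averaged
# reconstructions.

fitted_tiny <- function() {
  cached("fitted_tiny", {
    coh <- tiny_cohort()
    # downsample normalized volumes to the tiny 16^3 architecture by
    # striding, keeping the planted structure
    vols <- lapply(coh$norm, function(v) v[c(TRUE, FALSE), c(TRUE, FALSE),
                                           c(TRUE, FALSE)])
    split <- split_by_subject(coh$table, seed = 5)
    cfg <- train_config(latent_dim = 4L, epochs = 2L, seed = 2L,
                        batch_size = 8L)
    fit <- vae_fit(vols, coh$table, split, cfg,
                   similarity_spec(sim_term(0, "SCORE", 2e-4)),
                   arch = tiny_arch(4L))
    list(fit = fit, coh = coh, vols = vols, split = split)
  })
}

test_that("encoding is deterministic, one row per scan, covariates joined", {
  ft <- fitted_tiny()
  lat1 <- encode_cohort(ft$fit$model, ft$vols, ft$coh$table)
  lat2 <- encode_cohort(ft$fit$model, ft$vols, ft$coh$table)
  expect_identical(lat1, lat2)
  expect_equal(nrow(lat1), length(ft$vols))
  expect_true(all(c("PTID", "SCORE", "z0", "z3") %in% names(lat1)))
  expect_error(encode_cohort(ft$fit$model, list(array(0, c(8, 8, 8))),
                             ft$coh$table[1, ]), "does not match")
})

test_that("zeroed posterior heads encode every scan to the origin", {
  m <- build_model(tiny_arch(), seed = 1)
  m$fc_mu$params$W[] <- 0
  m$fc_mu$params$b[] <- 0
  vols <- lapply(1:3, function(i) array(runif(16^3), c(16, 16, 16)))
  enc <- encode_volumes(m, vols)
  expect_equal(enc$mu, matrix(0, 4, 3))
})

test_that("correlate_latents matches cor.test and flags degenerate columns", {
  set.seed(20)
  lat <- tibble::tibble(PTID = paste0("s", 1:50),
                        z0 = rnorm(50), z1 = rnorm(50),
                        SCORE = rnorm(50), CONST = rep(1, 50))
  lat$SCORE[3] <- NA
  out <- correlate_latents(lat, c("SCORE", "CONST"))
  ct <- cor.test(lat$z0[-3], lat$SCORE[-3])
  row <- out[out$latent == "z0" & out$covariate == "SCORE", ]
  expect_equal(row$r, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(row$p, ct$p.value, tolerance = 1e-10)
  expect_equal(row$n, 49)
  expect_true(all(out$undefined[out$covariate == "CONST"]))
  # self-correlation r = 1
  lat2 <- tibble::tibble(z0 = rnorm(20))
  lat2$COPY <- lat2$z0
  expect_equal(correlate_latents(lat2, "COPY")$r, 1, tolerance = 1e-12)
})

test_that("latents uncorrelated with an independent covariate stay near 0", {
  set.seed(21)
  lat <- tibble::tibble(z0 = rnorm(1000), z1 = rnorm(1000), Y = rnorm(1000))
  out <- correlate_latents(lat, "Y")
  expect_true(all(abs(out$r) < 0.1))
})

test_that("traversal decodes k volumes deterministically, in-range only", {
  ft <- fitted_tiny()
  out <- traverse_latent(ft$fit$model, 0, c(-1, 0, 1))
  expect_length(out, 3)
  expect_equal(dim(out[[1]]), c(16L, 16L, 16L))
  origin <- traverse_latent(ft$fit$model, 0, 0)
  expect_equal(out[[2]], origin[[1]])
  expect_error(traverse_latent(ft$fit$model, 9, 0), "out of range")
})

test_that("averaged reconstructions are seeded and exact when d = 2", {
  ft <- fitted_tiny()
  g1 <- average_reconstructions(ft$fit$model, c(-1, 1), c(-1, 1),
                                n_samples = 4, seed = 3)
  g2 <- average_reconstructions(ft$fit$model, c(-1, 1), c(-1, 1),
                                n_samples = 4, seed = 3)
  expect_identical(g1$volumes, g2$volumes)
  expect_equal(nrow(g1$grid), 4)
  # d = 2: no free dimensions, averaging equals a single decode
  m2 <- build_model(tiny_arch(latent_dim = 2L), seed = 4)
  ga <- average_reconstructions(m2, 0.5, -0.5, n_samples = 7, seed = 1)
  direct <- decode_latent(m2, c(0.5, -0.5))
  expect_equal(ga$volumes[[1]], direct[[1]], tolerance = 1e-12)
})

test_that("cell means converge at the Monte-Carlo rate", {
  ft <- fitted_tiny()
  big <- average_reconstructions(ft$fit$model, 0, 0, n_samples = 300,
                                 seed = 11)
  small <- average_reconstructions(ft$fit$model, 0, 0, n_samples = 100,
                                   seed = 12)
  # voxelwise sd of single decodes around the cell mean
  set.seed(13)
  d <- ft$fit$model$spec$latent_dim
  zs <- matrix(rnorm(d * 50), d, 50)
  zs[1:2, ] <- 0
  dec <- decode_latent(ft$fit$model, zs)
  sds <- apply(vapply(dec, as.numeric, numeric(16^3)), 1, sd)
  diff_rms <- sqrt(mean((big$volumes[[1]] - small$volumes[[1]])^2))
  expect_lt(diff_rms, 2 * sqrt(mean(sds^2)) / sqrt(100))
})
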