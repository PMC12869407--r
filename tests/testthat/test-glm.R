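# Voxel-wise GLM: exact recovery on constructed grids, OLS oracle
# equivalence, residual orthogonality, permutation invariance, ROI
# summaries, interaction ratio.

synthetic_grid <- function(f, z0 = seq(-1.5, 1.5, length.out = 5),
                           z1 = seq(-1, 1, length.out = 5),
                           shape = c(6L, 6L, 6L), noise_sd = 0, seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(z0 = z0, z1 = z1, KEEP.OUT.ATTRS = FALSE)
  vols <- lapply(seq_len(nrow(grid)), function(i) {
    array(f(grid$z0[i], grid$z1[i]) +
            rnorm(prod(shape), 0, noise_sd), dim = shape)
  })
  structure(list(grid = tibble::tibble(cell = seq_len(nrow(grid)),
                                       z0 = grid$z0, z1 = grid$z1),
                 volumes = vols, n_samples = 1L, seed = seed,
                 guided_dims = c(0L, 1L)),
            class = "recon_grid")
}

test_that("an exactly linear grid is recovered to machine precision", {
  rg <- synthetic_grid(function(z0, z1) 2 - 0.5 * z0 + 0.1 * z1)
  maps <- fit_voxelwise_glm(rg, standardize = FALSE)
  expect_equal(max(abs(maps$beta$z0 + 0.5)), 0, tolerance = 1e-8)
  expect_equal(max(abs(maps$beta$z1 - 0.1)), 0, tolerance = 1e-8)
  expect_equal(max(abs(maps$gamma$`z0:z1`)), 0, tolerance = 1e-8)
  expect_equal(max(abs(maps$intercept - 2)), 0, tolerance = 1e-8)
})

test_that("a constant grid yields zero effects and the constant intercept", {
  rg <- synthetic_grid(function(z0, z1) 3.7)
  maps <- fit_voxelwise_glm(rg)
  expect_equal(max(abs(maps$beta$z0)), 0, tolerance = 1e-10)
  expect_equal(max(abs(maps$beta$z1)), 0, tolerance = 1e-10)
  expect_equal(max(abs(maps$intercept - 3.7)), 0, tolerance = 1e-10)
})

test_that("noisy grids match the per-voxel normal-equations oracle", {
  rg <- synthetic_grid(function(z0, z1) 1 + 0.3 * z0 - 0.2 * z1 + 0.1 * z0 * z1,
                       noise_sd = 0.2, seed = 5)
  maps <- fit_voxelwise_glm(rg, standardize = FALSE)
  X <- cbind(1, rg$grid$z0, rg$grid$z1, rg$grid$z0 * rg$grid$z1)
  XtXi <- solve(t(X) %*% X)
  idx <- cbind(c(1, 3, 5), c(2, 4, 1), c(3, 2, 6))
  for (r in 1:3) {
    y <- vapply(rg$volumes, function(v) v[idx[r, 1], idx[r, 2], idx[r, 3]], 1)
    beta <- XtXi %*% t(X) %*% y
    expect_equal(maps$intercept[idx[r, 1], idx[r, 2], idx[r, 3]], beta[1],
                 tolerance = 1e-8)
    expect_equal(maps$beta$z0[idx[r, 1], idx[r, 2], idx[r, 3]], beta[2],
                 tolerance = 1e-8)
    expect_equal(maps$gamma$`z0:z1`[idx[r, 1], idx[r, 2], idx[r, 3]], beta[4],
                 tolerance = 1e-8)
  }
})

test_that("residuals are orthogonal to the design at every voxel", {
  rg <- synthetic_grid(function(z0, z1) 0.5 + z0 - z1, noise_sd = 0.3,
                       seed = 6)
  maps <- fit_voxelwise_glm(rg)
  X <- maps$design$X
  Y <- t(vapply(rg$volumes, as.numeric, numeric(6^3)))
  coefs <- rbind(as.numeric(maps$intercept), as.numeric(maps$beta$z0),
                 as.numeric(maps$beta$z1), as.numeric(maps$gamma$`z0:z1`))
  res <- Y - X %*% coefs
  expect_lt(max(abs(t(X) %*% res)), 1e-6)
})

test_that("permuting cell order leaves the maps unchanged", {
  rg <- synthetic_grid(function(z0, z1) 1 + 0.4 * z0, noise_sd = 0.1,
                       seed = 7)
  maps1 <- fit_voxelwise_glm(rg)
  set.seed(8)
  perm <- sample(nrow(rg$grid))
  rg2 <- rg
  rg2$grid <- rg$grid[perm, ]
  rg2$grid$cell <- seq_len(nrow(rg$grid))
  rg2$volumes <- rg$volumes[perm]
  maps2 <- fit_voxelwise_glm(rg2)
  expect_equal(maps1$beta$z0, maps2$beta$z0, tolerance = 1e-10)
  expect_equal(maps1$intercept, maps2$intercept, tolerance = 1e-10)
})

test_that("degenerate grids fail naming the collinear columns", {
  rg <- synthetic_grid(function(z0, z1) z0, z0 = rep(1, 3),
                       z1 = seq(-1, 1, length.out = 5))
  expect_error(fit_voxelwise_glm(rg, standardize = FALSE), "collinear")
  rg2 <- synthetic_grid(function(z0, z1) z0, z0 = c(-1, 1), z1 = c(-1, 1))
  rg2$volumes <- rg2$volumes[1:3]
  rg2$grid <- rg2$grid[1:3, ]
  expect_error(fit_voxelwise_glm(rg2), "more grid cells")
})

test_that("roi_summary matches brute-force masked statistics", {
  rg <- synthetic_grid(function(z0, z1) 1 - 0.5 * z0, noise_sd = 0.05,
                       seed = 9)
  maps <- fit_voxelwise_glm(rg)
  mask <- array(FALSE, dim(maps$intercept))
  mask[2:4, 2:4, 2:4] <- TRUE
  rs <- roi_summary(maps, mask)
  row <- rs[rs$coefficient == "z0" & rs$region == "inside", ]
  expect_equal(row$mean, mean(maps$beta$z0[mask]), tolerance = 1e-12)
  expect_equal(row$mean_abs, mean(abs(maps$beta$z0[mask])), tolerance = 1e-12)
  expect_equal(row$sd, sd(maps$beta$z0[mask]), tolerance = 1e-12)
  # full mask equals whole-map statistics
  full <- roi_summary(maps, array(TRUE, dim(mask)))
  frow <- full[full$coefficient == "intercept" & full$region == "inside", ]
  expect_equal(frow$mean, mean(maps$intercept), tolerance = 1e-12)
  expect_error(roi_summary(maps, array(FALSE, dim(mask))), "empty mask")
})

test_that("interaction ratio separates additive from interacting designs", {
  add <- fit_voxelwise_glm(synthetic_grid(
    function(z0, z1) 1 + 0.5 * z0 + 0.4 * z1, noise_sd = 0.02, seed = 10))
  expect_lt(interaction_ratio(add), 0.05)
  inter <- fit_voxelwise_glm(synthetic_grid(
    function(z0, z1) 1 + 0.5 * z0 + 0.5 * z0 * z1, noise_sd = 0.02,
    seed = 11), standardize = FALSE)
  expect_equal(interaction_ratio(inter), 1, tolerance = 0.1)
  zero <- fit_voxelwise_glm(synthetic_grid(function(z0, z1) 0))
  ir <- interaction_ratio(zero)
  expect_true(is.na(ir))
  expect_true(attr(ir, "undefined"))
})
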