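# Phantom cohort generator: counts, determinism, planted effects, masks.

test_that("cohort has the configured counts and reproduces bit-identically", {
  cfg <- phantom_config(n_subjects = 10L, scans_per_subject = 2L, seed = 7L)
  coh <- generate_cohort(cfg)
  expect_length(coh$volumes, 20)
  expect_equal(nrow(coh$table), 20)
  expect_equal(length(unique(coh$table$PTID)), 10)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh$table, coh2$table)
  expect_identical(coh$volumes, coh2$volumes)
})

test_that("with zero effects and confounders all volumes equal the template", {
  cfg <- phantom_config(n_subjects = 3L, scans_per_subject = 2L,
                        severity_effect = 0, spared_effect = 0,
                        age_effect = 0, drift_sd = 0, translation_sd = 0,
                        rotation_sd = 0, scale_sd = 0, gain_sd = 0,
                        noise_sd = 0, seed = 1L)
  coh <- generate_cohort(cfg)
  tmpl <- coh$truth$template
  for (v in coh$volumes) expect_equal(v, tmpl, tolerance = 1e-12)
})

test_that("noise-only cohort has voxelwise variance noise_sd^2", {
  cfg <- phantom_config(n_subjects = 60L, scans_per_subject = 1L,
                        severity_effect = 0, spared_effect = 0,
                        age_effect = 0, drift_sd = 0, translation_sd = 0,
                        rotation_sd = 0, scale_sd = 0, gain_sd = 0,
                        noise_sd = 0.1, volume_shape = c(16L, 16L, 16L),
                        seed = 2L)
  coh <- generate_cohort(cfg)
  stack <- vapply(coh$volumes, as.numeric, numeric(16^3))
  vv <- apply(stack, 1, var)
  expect_equal(mean(vv), 0.01, tolerance = 0.05)
})

test_that("affected-region mean intensity decreases in severity", {
  cfg <- phantom_config(n_subjects = 15L, scans_per_subject = 1L,
                        drift_sd = 0, translation_sd = 0, rotation_sd = 0,
                        scale_sd = 0, gain_sd = 0, noise_sd = 0, seed = 3L)
  coh <- generate_cohort(cfg)
  mask <- coh$truth$affected_mask
  means <- vapply(coh$volumes, function(v) mean(v[mask]), 1)
  ord <- order(coh$truth$severity)
  expect_true(all(diff(means[ord]) < 0))
})

test_that("structural covariate hits the target correlation with -severity", {
  coh <- generate_cohort(phantom_config(n_subjects = 300L,
                                        scans_per_subject = 1L,
                                        volume_shape = c(16L, 16L, 16L),
                                        volume_corr_target = 0.48,
                                        seed = 4L))
  per_subject <- coh$table[!duplicated(coh$table$PTID), ]
  r <- cor(per_subject$HIPPO_NV, -coh$truth$severity)
  expect_lt(abs(r - 0.48), 0.1)
})

test_that("masks are pairwise disjoint, nonempty, and match brute force", {
  coh <- tiny_cohort()
  m <- ground_truth_masks(coh$truth)
  expect_true(all(vapply(m, sum, 1) >= 1))
  expect_equal(sum(m$affected & m$spared), 0)
  expect_equal(sum(m$affected & m$age), 0)
  expect_equal(sum(m$spared & m$age), 0)
  # brute-force voxel count of one blob's support above the mask level
  blobs <- simvae:::phantom_blobs()
  shape <- dim(m$age)
  ax <- lapply(shape, function(n) seq(-1, 1, length.out = n))
  cnt <- 0L
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
    for (k in seq_len(shape[3])) {
      u <- c(ax[[1]][i], ax[[2]][j], ax[[3]][k])
      d2 <- sum((u - blobs$age$center)^2)
      if (exp(-d2 / (2 * blobs$age$radius^2)) > 0.6) cnt <- cnt + 1L
    }
  expect_equal(sum(m$age), cnt)
})

test_that("diagnosis labels follow severity tertiles and scores are ADAS-like", {
  coh <- tiny_cohort()
  per_subject <- coh$table[!duplicated(coh$table$PTID), ]
  sev <- coh$truth$severity
  expect_true(all(sev[per_subject$DX == "AD"] >
                    max(sev[per_subject$DX == "HC"])))
  expect_true(all(coh$table$SCORE > 10 & coh$table$SCORE < 35))
  # score is monotone in per-scan severity
  st <- coh$truth$scan_truth
  expect_equal(order(coh$table$SCORE), order(st$severity_scan))
})

test_that("degenerate volume shape and bad sds are rejected", {
  expect_error(phantom_config(volume_shape = c(8L, 8L, 8L)), "blob support")
  expect_error(phantom_config(noise_sd = -1), "sd parameters")
  expect_error(phantom_config(volume_corr_target = 1.2), "volume_corr_target")
})

test_that("extreme severity effects clamp at zero and raise the flag", {
  cfg <- phantom_config(n_subjects = 20L, scans_per_subject = 1L,
                        severity_effect = 2, translation_sd = 0,
                        rotation_sd = 0, scale_sd = 0, gain_sd = 0,
                        noise_sd = 0, drift_sd = 0, seed = 5L)
  coh <- generate_cohort(cfg)
  expect_gt(coh$truth$n_clamped, 0)
  for (v in coh$volumes) expect_true(all(v >= 0))
})

test_that("affine resampling moves the volume as a pull-back of the forward map", {
  # pure translation: content shifts by +t (forward), sampled via inverse
  v <- array(0, c(16, 16, 16))
  v[8, 8, 8] <- 1
  out <- simvae:::.affine_resample3d(v, diag(3), c(-2, 0, 0))
  expect_equal(unname(which(out == max(out), arr.ind = TRUE)[1, 1]), 10L)
})
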