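# Synthetic 3D phantom cohort with planted severity/age effects and
# affine/intensity confounders, standing in for an access-restricted
# longitudinal FDG-PET cohort. The template is a fixed sum of Gaussian
# blobs; disease severity multiplicatively depresses intensity in an
# "affected" region and mildly raises it in a "spared" region, age modulates
# a separate region, and per-scan confounders (small rigid+scale affines,
# global gain jitter, additive noise) mimic residual coregistration and
# acquisition variability.

# Blob geometry emulates the spatial organisation of AD hypometabolism:
# the affected region is an extensive bilateral cortical territory (a
# sizeable fraction of the brain, as the default-mode and fronto-parietal
# networks are), the spared region a compact sensorimotor-like strip, the
# age region a separate territory, and `reference` a bright
# disease-independent structure (pons/cerebellum-like). The reference is
# the brightest tissue for every subject, so per-volume percentile
# normalization keys on it rather than on disease-modulated tissue —
# without it, a focal deficit leaks into a global intensity rescaling.
# Region masks are the blob profiles above 0.6 of their peak and are
# pairwise disjoint by construction.
phantom_blobs <- function() {
  list(
    brain    = list(center = c(0, 0, 0),          radius = 0.55, amp = 0.8),
    affectedL = list(center = c(-0.45, -0.20, 0.00), radius = 0.30, amp = 0.35),
    affectedR = list(center = c( 0.45, -0.20, 0.00), radius = 0.30, amp = 0.35),
    spared   = list(center = c(0, 0.45, 0.35),    radius = 0.18, amp = 0.40),
    age      = list(center = c(0, -0.60, 0.35),   radius = 0.30, amp = 0.40),
    reference = list(center = c(0, -0.05, -0.50), radius = 0.20, amp = 0.90)
  )
}

# Disease/age burden: a smooth, strictly increasing rectifier of the
# standardized factor. Hypometabolism is a deficit process — subjects below
# the cohort mean carry essentially no burden rather than a symmetric
# intensity surplus; the slope approaches 1 per unit above the mean.
phantom_burden <- function(s) log1p(exp(2 * (s + 1))) / 2

# Gaussian blob profile exp(-||u - c||^2 / (2 r^2)) on the [-1, 1]^3 grid.
blob_field <- function(shape, blob) {
  ax <- lapply(shape, function(n) seq(-1, 1, length.out = n))
  d2 <- outer(outer((ax[[1]] - blob$center[1])^2,
                    (ax[[2]] - blob$center[2])^2, "+"),
              (ax[[3]] - blob$center[3])^2, "+")
  exp(-d2 / (2 * blob$radius^2))
}

phantom_template <- function(shape) {
  blobs <- phantom_blobs()
  tmpl <- array(0, dim = shape)
  for (b in blobs) tmpl <- tmpl + b$amp * blob_field(shape, b)
  tmpl
}

# A region mask is the blob's own profile above `level` (default 0.6 of its
# peak), i.e. within about one radius of the center.
phantom_masks <- function(shape, level = 0.6) {
  blobs <- phantom_blobs()
  list(
    affected = blob_field(shape, blobs$affectedL) > level |
               blob_field(shape, blobs$affectedR) > level,
    spared = blob_field(shape, blobs$spared) > level,
    age = blob_field(shape, blobs$age) > level
  )
}

#' Phantom cohort configuration
#'
#' Defaults define the study conditions used throughout: a 300-subject,
#' two-scans-per-subject cohort of 32^3 volumes with a moderate planted
#' severity effect, a milder spared-region increase and age effect, small
#' residual affine confounders (what survives rigid coregistration),
#' 5 percent global gain jitter, and additive noise.
#'
#' @param volume_shape integer triple; each axis must be at least 16 voxels
#'   so the template blobs are resolved.
#' @param n_subjects,scans_per_subject cohort size.
#' @param severity_effect fractional intensity drop in the affected mask per
#'   unit severity burden (a smooth rectifier of standardized severity:
#'   deficit only, no surplus for subjects below the cohort mean).
#' @param spared_effect fractional increase in the spared mask per unit
#'   standardized severity.
#' @param age_effect fractional drop in the age mask per unit age burden
#'   (same rectified form, of standardized age).
#' @param drift_sd longitudinal severity drift between scans of one subject.
#' @param translation_sd,rotation_sd,scale_sd affine confounder scales
#'   (voxels, degrees, fraction).
#' @param gain_sd global multiplicative intensity jitter (fraction).
#' @param noise_sd additive Gaussian noise (intensity units).
#' @param volume_corr_target target correlation between the
#'   hippocampus-like structural covariate and negative severity; the other
#'   three covariates scale with it in the ratios 0.45/0.48, 0.37/0.48 and
#'   0.15/0.48.
#' @param seed integer seed; the cohort is bit-reproducible from it.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(volume_shape = c(32L, 32L, 32L),
                           n_subjects = 300L, scans_per_subject = 2L,
                           severity_effect = 0.30, spared_effect = 0.10,
                           age_effect = 0.30, drift_sd = 0.05,
                           translation_sd = 0.75, rotation_sd = 3,
                           scale_sd = 0.03, gain_sd = 0.05,
                           noise_sd = 0.02, volume_corr_target = 0.48,
                           seed = 1L) {
  stopifnot(length(volume_shape) == 3, n_subjects >= 1,
            scans_per_subject >= 1)
  sds <- c(drift_sd, translation_sd, rotation_sd, scale_sd, gain_sd, noise_sd)
  if (any(sds < 0)) stop("all sd parameters must be >= 0")
  if (abs(volume_corr_target) >= 1)
    stop("volume_corr_target must lie in (-1, 1)")
  if (any(volume_shape < 16))
    stop("volume_shape ", paste(volume_shape, collapse = "x"),
         " is below the template blob support (each axis must be >= 16)")
  structure(list(volume_shape = as.integer(volume_shape),
                 n_subjects = as.integer(n_subjects),
                 scans_per_subject = as.integer(scans_per_subject),
                 severity_effect = severity_effect,
                 spared_effect = spared_effect, age_effect = age_effect,
                 drift_sd = drift_sd, translation_sd = translation_sd,
                 rotation_sd = rotation_sd, scale_sd = scale_sd,
                 gain_sd = gain_sd, noise_sd = noise_sd,
                 volume_corr_target = volume_corr_target,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Generate a synthetic phantom cohort
#'
#' Draws per-subject severity (standard normal) and age (normal with mean
#' 72.8 and sd 7.3 years), derives an ADAS13-like score
#' `10 + 25 * sigmoid(severity)` and tertile diagnosis labels (HC/MCI/AD in
#' increasing severity), plants the regional intensity effects in the
#' template (deficits scale with a rectified burden of the standardized
#' factor, so the affected and age territories darken with disease and age
#' but never brighten beyond baseline, and the bright reference territory
#' stays the intensity ceiling for every scan), applies per-scan affine
#' resampling (trilinear, zero-padded), global gain and additive noise, and
#' constructs four structural-volume covariates as noisy linear functions
#' of negative severity hitting the configured correlation targets in
#' expectation.
#'
#' @param config a [phantom_config()].
#' @return list with `table` (one covariate row per scan: PTID, SCANID,
#'   SCORE, AGE, DX, HIPPO_NV, MTL_NV, ENT_NV, FUSI_NV), `volumes` (list of
#'   3D arrays, parallel to `table` rows), and `truth` (a `phantom_truth`
#'   with region masks, per-subject severity/age, per-scan affine and gain
#'   parameters, and `n_clamped`, the number of scans whose planted effects
#'   drove intensities negative before clamping).
#' @export
generate_cohort <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  shape <- config$volume_shape
  tmpl <- phantom_template(shape)
  masks <- phantom_masks(shape)
  n <- config$n_subjects
  k <- config$scans_per_subject

  severity <- stats::rnorm(n)
  age <- stats::rnorm(n, 72.8, 7.3)
  dx_cut <- stats::quantile(severity, c(1 / 3, 2 / 3), type = 7)
  dx <- cut(severity, c(-Inf, dx_cut, Inf), labels = c("HC", "MCI", "AD"))

  rho_ratios <- c(HIPPO_NV = 1, MTL_NV = 0.45 / 0.48, ENT_NV = 0.37 / 0.48,
                  FUSI_NV = 0.15 / 0.48)
  vols_cov <- sapply(rho_ratios, function(f) {
    rho <- config$volume_corr_target * f
    rho * (-severity) + sqrt(1 - rho^2) * stats::rnorm(n)
  })

  n_scan <- n * k
  volumes <- vector("list", n_scan)
  rows <- vector("list", n_scan)
  scan_truth <- vector("list", n_scan)
  n_clamped <- 0L
  i <- 0L
  for (s in seq_len(n)) {
    for (v in seq_len(k)) {
      i <- i + 1L
      s_scan <- severity[s] + if (k > 1) stats::rnorm(1, 0, config$drift_sd) else 0
      age_scan <- age[s] + (v - 1)  # annual follow-up visits
      a_std <- (age_scan - 72.8) / 7.3
      img <- tmpl
      img[masks$affected] <- img[masks$affected] *
        (1 - config$severity_effect * phantom_burden(s_scan))
      img[masks$spared] <- img[masks$spared] *
        (1 + config$spared_effect * s_scan)
      img[masks$age] <- img[masks$age] *
        (1 - config$age_effect * phantom_burden(a_std))
      clamped <- any(img < 0)
      if (clamped) {
        img[img < 0] <- 0
        n_clamped <- n_clamped + 1L
      }
      ang <- stats::rnorm(3, 0, config$rotation_sd)
      scl <- 1 + stats::rnorm(3, 0, config$scale_sd)
      trs <- stats::rnorm(3, 0, config$translation_sd)
      if (config$rotation_sd > 0 || config$scale_sd > 0 ||
          config$translation_sd > 0) {
        fwd <- diag(scl) %*% rotation_matrix(ang)
        M <- solve(fwd)
        img <- .affine_resample3d(img, M, as.numeric(-M %*% trs))
      }
      gain <- 1 + if (config$gain_sd > 0) stats::rnorm(1, 0, config$gain_sd) else 0
      img <- img * gain
      if (config$noise_sd > 0)
        img <- img + array(stats::rnorm(length(img), 0, config$noise_sd),
                           dim = shape)
      volumes[[i]] <- img
      rows[[i]] <- tibble::tibble(
        PTID = sprintf("S%04d", s), SCANID = sprintf("S%04d_V%02d", s, v),
        SCORE = 10 + 25 / (1 + exp(-s_scan)), AGE = age_scan,
        DX = as.character(dx[s]),
        HIPPO_NV = vols_cov[s, "HIPPO_NV"], MTL_NV = vols_cov[s, "MTL_NV"],
        ENT_NV = vols_cov[s, "ENT_NV"], FUSI_NV = vols_cov[s, "FUSI_NV"])
      scan_truth[[i]] <- tibble::tibble(
        PTID = rows[[i]]$PTID, SCANID = rows[[i]]$SCANID,
        severity_scan = s_scan, gain = gain, clamped = clamped,
        rot_x = ang[1], rot_y = ang[2], rot_z = ang[3],
        scale_x = scl[1], scale_y = scl[2], scale_z = scl[3],
        trans_x = trs[1], trans_y = trs[2], trans_z = trs[3])
    }
  }
  truth <- structure(list(
    affected_mask = masks$affected, spared_mask = masks$spared,
    age_mask = masks$age, severity = severity, age = age,
    template = tmpl, scan_truth = dplyr::bind_rows(scan_truth),
    n_clamped = n_clamped, config = config), class = "phantom_truth")
  list(table = dplyr::bind_rows(rows), volumes = volumes, truth = truth)
}

#' Ground-truth region masks
#'
#' Returns the affected/spared/age boolean masks in template space (before
#' any per-scan affine), pairwise disjoint and nonempty by construction.
#'
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @return named list of three logical arrays.
#' @export
ground_truth_masks <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  list(affected = truth$affected_mask, spared = truth$spared_mask,
       age = truth$age_mask)
}
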