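# simvae

Semi-supervised variational autoencoders with similarity-regularized
latents, for 3D brain volumes.

## The problem

Neuroimaging cohorts are high-dimensional, and the quantities clinicians
care about — disease severity, age — are entangled in the images with
nuisance variation: residual misalignment after rigid coregistration,
intensity gain differences, inter-subject variability. `simvae` implements
a semi-supervised 3D convolutional β-VAE whose training objective adds, on
top of reconstruction and KL terms, one *similarity regularizer per chosen
latent dimension*:

    L = MSE(x, x̂) + β · KL(q(z|x) ‖ N(0, I)) + Σ_j α_j · ( −r(z_kj, y_j) )

Each term `−r(z_k, y)` is the negative batch-level correlation (Pearson, or
a differentiable soft-rank Spearman) between one latent dimension and an
external covariate such as a cognitive score or age. Minimizing the total
loss maximizes those correlations, so after training the chosen dimensions
function as interpretable *latent biomarkers*: z0 orders scans along
disease severity, z1 along age, and the remaining dimensions absorb
confounders. The package targets users who want to study this model class
— its convergence regimes, its disentanglement behavior, and its generative
interpretability — on a single CPU.

Around the core model the package provides:

- **`phantom`** — a synthetic multi-subject, longitudinal 3D cohort with
  planted severity/age territories, affine/gain/noise confounders, and
  ground-truth region masks (real FDG-PET cohorts of the required size are
  access-restricted);
- **`io_preproc`** — NIfTI-1 read/write, percentile + exponential-contrast
  intensity normalization, missing-covariate exclusion, leakage-free
  subject-level splitting (65/15/20);
- **`model` / training** — the 3D conv VAE (encoder/decoder built from a
  validated architecture spec, reparameterization, all loss components with
  hand-derived gradients, Adam), implemented in R + C++ since no
  deep-learning framework is involved;
- **`diagnostics`** — posterior-collapse phase diagrams: latent-mean
  dispersion D_mu over (latent dim × β) grids, converged |r(z0, score)|
  over (β × α) grids, with regime labels;
- **`latentmap`** — cohort encoding, latent-covariate correlation tables,
  single-dimension latent traversal, and averaged generative
  reconstructions over a (z0, z1) grid;
- **`glm`** — a voxel-wise OLS GLM over the averaged reconstructions
  (intercept, main effects, interaction, residual variance maps), ROI
  summaries against ground-truth masks, and an interaction-to-main-effect
  disentanglement ratio;
- **`evalstats`** — bootstrap logistic-regression classification (AD vs
  HC) from latent features, per-dimension discriminability, and a
  guided-vs-ablated (α = 0) comparison.

See the vignette (`vignettes/similarity-regularized-vae.Rmd`) for the full
methods account.

## Worked example

```r
library(simvae)

# a 300-subject, 2-scans-per-subject phantom cohort of 32^3 volumes
coh   <- generate_cohort(phantom_config(seed = 31))
vols  <- lapply(coh$volumes, normalize_intensity)
split <- split_by_subject(coh$table, seed = 31)

# guide z0 with the cognitive score and z1 with age
sim <- similarity_spec(sim_term(0, "SCORE", 2e-4),
                       sim_term(1, "AGE",   2e-4))
fit <- vae_fit(vols, coh$table, split,
               train_config(latent_dim = 8, beta = 1e-4, epochs = 25,
                            seed = 1),
               sim)

lat_all <- encode_cohort(fit$model, vols, coh$table)
lat <- lat_all[lat_all$PTID %in% split$test, ]
correlate_latents(lat, c("SCORE", "AGE", "HIPPO_NV"))
```

On this configuration (seeds as above) the held-out correlation table
starts:

```
  latent covariate     n        r        p undefined
  z0     SCORE       120  0.874   9.2e-39 FALSE
  z0     AGE         120  0.078   4.0e-01 FALSE
  z0     HIPPO_NV    120 -0.361   5.1e-05 FALSE
  z1     SCORE       120  0.003   9.8e-01 FALSE
  z1     AGE         120  0.511   2.5e-09 FALSE
  ...
```

The score-guided dimension z0 carries the severity signal and the
age-guided dimension z1 the age signal on held-out subjects (each nearly
uncorrelated with the other's covariate), and the hippocampus-like
structural covariate — planted to shrink with severity — correlates with
z0 with the opposite sign. Alignment strength is seed-dependent at this
scale: roughly one initialization in three fails to latch on (the
acceptance tests assess three training seeds for exactly this reason).
Downstream:

```r
r0 <- latent_range(lat, 0); r1 <- latent_range(lat, 1)
recon <- average_reconstructions(fit$model,
                                 seq(r0[1], r0[2], length.out = 7),
                                 seq(r1[1], r1[2], length.out = 7),
                                 n_samples = 64, seed = 7,
                                 free_sd = latent_sds(lat),
                                 free_mean = latent_means(lat))
maps <- fit_voxelwise_glm(recon)
roi_summary(maps, ground_truth_masks(coh$truth)$affected)
interaction_ratio(maps)   # 0.154: severity and age act near-additively

classify_bootstrap(lat_all, split, "z0", replicates = 100, seed = 5)$summary
```

The β0 map concentrates in the planted affected territory — mean |β0|
inside the mask is 3.7x the background — the interaction map is small
(the generator is additive in severity and age), and z0 alone separates
AD from HC with balanced accuracy 0.96 on this run.

A thin command-line wrapper over the same functions is installed at
`inst/cli/simvae.R` (subcommands `simulate`, `train`, `analyze`, `sweep`,
`ablate`), configured by YAML and a single global seed.

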