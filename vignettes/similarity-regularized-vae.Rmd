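---
title: "Similarity-regularized VAEs for 3D brain volumes: model, phantom, and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-regularized VAEs for 3D brain volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(simvae)
```

## The model

`simvae` implements a semi-supervised 3D convolutional variational
autoencoder for brain volumes. A convolutional encoder maps a volume $x$ to
a diagonal Gaussian posterior $q(z \mid x) = \mathcal{N}(\mu, \mathrm{diag}\,\sigma^2)$
over a $d$-dimensional latent code; a transposed-convolutional decoder maps
codes back to volumes. Training minimizes

$$
\mathcal{L} \;=\; \underbrace{\tfrac1N\sum_i (x_i - \hat x_i)^2}_{\text{reconstruction (MSE)}}
\;+\; \beta\, \underbrace{\tfrac12\sum_{i=1}^d\!\big(\mu_i^2 + \sigma_i^2 - 1 - \log\sigma_i^2\big)}_{D_{\mathrm{KL}}\!\left(q(z\mid x)\,\|\,\mathcal{N}(0,I)\right)}
\;+\; \sum_j \alpha_j\, \mathcal{L}^{(j)}_{\text{similarity}},
\qquad
\mathcal{L}^{(j)}_{\text{similarity}} = -\,r\!\left(z_{k_j},\, y_j\right),
$$

where each similarity term ties one chosen latent dimension $z_{k_j}$ to an
external covariate $y_j$ (a cognitive score, age, a biomarker volume)
through the negative of a batch-level correlation. Minimizing the total
therefore maximizes each targeted correlation while the KL term keeps the
latent space close to the standard normal prior (the beta-VAE
regularization). The intended use is a latent *biomarker*: after training
with $-r(z_0, \text{score})$ and $-r(z_1, \text{age})$, the first latent
dimension orders subjects along disease severity, the second along age, and
the remaining dimensions absorb confounding variation (affine misalignment,
intensity gain, inter-subject variability).

Two sign conventions are worth stating once. The Gaussian KL closed form is
often printed with the opposite sign and then *subtracted* in the total
loss; the two flips cancel, and the implementation adds the non-negative
divergence penalty shown above (`kl_gaussian()` is $\ge 0$, zero exactly at
the prior; this is asserted in the tests). Second, the similarity loss is
the *signed* $-r$, not $-|r|$: $|r|$ has a gradient discontinuity at zero,
and a term initialized near $r \approx 0$ would receive unstable gradients.
The model may therefore converge to either sign of alignment; reporting
uses $|r|$.

### Correlation within a batch

Both similarity metrics are computed per mini-batch, as stochastic
optimization requires. Pairs whose covariate is missing are removed before
centering; the scan still contributes to reconstruction and KL. A batch
with fewer than two complete pairs, or zero variance in either vector,
contributes nothing for that term (the event is counted in the training
log). Batch-level correlation is a high-variance estimator — under
independence its standard deviation is roughly $1/\sqrt{B-1}$, about 0.38
at $B = 8$ — which is why the default batch size is 16 (the full-scale
reference configuration used 8 on a cohort about six times larger, where
many more optimization steps average the noise away).

The Pearson instance is exact. The Spearman instance must be
differentiable, so the latent batch is replaced by *soft ranks*
$\tilde r_i = 1 + \sum_{j \ne i} \sigma\!\big((z_i - z_j)/\tau\big)$
(pairwise logistic relaxations; $\tau$ defaults to $0.1 \cdot \mathrm{sd}(z)$),
while the covariate uses exact average ranks; both then enter the Pearson
formula. As $\tau \to 0$ the value converges to the exact Spearman
$-\rho$; `hard = TRUE` gives the exact rank statistic for evaluation.

### Architecture

The full-scale preset (`arch_preset("full")`) uses four stride-2
convolutions with kernels 11/7/5/3 and 32/64/128/256 channels over a
48x64x48 voxel input, flattening to 9216 features (256 channels x 3x4x3), a
256-wide fully connected layer, and two linear heads for $\mu$ and
$\log\sigma^2$; the decoder expands the code to 4608 features (128 x
3x4x3) and applies three transposed convolutions with kernels 3/4/11
followed by a 1-channel projection. Each (transposed) convolution is
followed by ReLU and batch normalization. Only this preset's shape
arithmetic is exercised in the tests; it is not trainable in reasonable
time on one CPU.

The desk preset (`arch_preset("desk")`) is the CPU-trainable reduction used
throughout: 32x32x32 inputs, encoder kernels 7/5/3/3 (strides 2) with
4/8/16/32 channels, a 64-wide fully connected layer, and a decoder of four
kernel-4 stride-2 transposed convolutions (16/8/4/4 channels) with a final
1x1x1 projection and no squashing output activation (inputs are normalized
to $[0,1]$ but the regression-style linear output trains more stably than a
saturating one at this scale). Encoder kernel sizes mirror the full-scale
design philosophy — large receptive fields first; the decoder uses kernel-4
stride-2 blocks because they upsample exactly 2x without checkerboard
artifacts and keep the high-resolution layers cheap.

The network, reverse-mode gradients (hand-derived per layer), and the Adam
optimizer are implemented in the package itself (R orchestration over C++
convolution kernels). Gradient correctness is established by
finite-difference checks in the test suite, and the convolution kernels are
cross-checked against an independent im2col-plus-matrix-multiply route.

### Training defaults

| parameter | default | note |
|---|---|---|
| latent dimension $d$ | 8 | reference configuration |
| $\beta$ | $10^{-4}$ | stable regime of the dispersion diagram |
| $\alpha_0 = \alpha_1$ | $2\times 10^{-4}$ | reference configuration |
| batch size | 16 | see batch-correlation variance above |
| learning rate | $10^{-3}$ | desk scale; the full-scale reference used $2\times10^{-5}$ with ~6x more data |
| epochs | 25 | validation alignment plateaus near epoch 10–12 at desk scale |
| optimizer | Adam | |

Everything is driven by a single integer seed (initialization, shuffling,
reparameterization noise), so a `(cohort, split, config)` triple reproduces
its loss history bit for bit.

## The phantom cohort

Real FDG-PET cohorts of the required size are access-restricted, so the
package ships a synthetic 3D phantom generator whose *planted ground truth*
makes recovery claims testable. The template is a fixed sum of Gaussian
blobs on a 32-cubed grid: a broad brain-like background, a bright
**reference** territory (pons/cerebellum-like, disease-independent), and
three disjoint effect territories:

- an **affected** territory (two bilateral blobs, ~2.7% of the volume)
  whose intensity is multiplied by $(1 - 0.30\, b(s))$ for subject severity
  $s \sim \mathcal{N}(0,1)$, where $b(\cdot)$ is a smooth rectifier
  ($b(s) = \tfrac12\log(1+e^{2(s+1)})$, approximately $\max(0, s+1)$):
  hypometabolism is a *deficit* — subjects below the cohort mean carry no
  burden rather than a symmetric intensity surplus. The territory emulates
  the spatially extensive involvement of the default-mode and
  fronto-parietal networks;
- a **spared** territory multiplied by $(1 + 0.10\, s)$ — the relative
  sensorimotor preservation/increase pattern;
- an **age** territory (~3% of the volume) multiplied by
  $(1 - 0.30\, b(\tilde a))$ for standardized age $\tilde a$ (cohort age
  $\sim \mathcal{N}(72.8, 7.3^2)$ years, one year between longitudinal
  visits) — aging-related decline in a territory separate from the disease
  one, with *no* severity-age interaction planted (the generator is
  additive in the two factors by construction, which is what the GLM
  interaction analysis should recover).

The reference territory matters more than it looks: per-volume percentile
normalization keys on the brightest voxels, and if those sit inside a
disease-modulated territory the normalization itself becomes
severity-dependent — a focal deficit then leaks into a *global* intensity
rescaling of every voxel, exactly the reference-region problem of real PET
quantification. The phantom's reference blob is the intensity ceiling for
every subject (the rectified burden guarantees no territory brightens
beyond baseline), which keeps the per-volume 99th percentile
severity-independent and the planted effects confined to their masks.

Each scan then receives the confounders that survive rigid-body
coregistration in real pipelines: a small random affine (translation sd
0.75 voxels, rotation sd 3 degrees, anisotropic scale sd 3%), applied by
trilinear pull-back resampling with zero padding; a global intensity gain
jitter (sd 5%); and additive Gaussian noise (sd 0.02). These magnitudes are
free parameters of the generator; the defaults are chosen so that affine
and gain variation — not disease — dominate the raw intensity variance,
matching the observation that most latent dimensions of an *unguided* model
encode affine and intensity confounders rather than disease. Severity
stays constant across a subject's scans up to a small longitudinal drift
(sd 0.05).

Covariates per scan: an ADAS13-like cognitive score
$10 + 25\,\mathrm{sigmoid}(s)$ (only monotonicity in severity matters);
tertile diagnosis labels HC/MCI/AD in increasing severity (ordinal
consistency is all downstream analyses need); and four structural-volume
covariates built as $\rho(-s) + \sqrt{1-\rho^2}\,\varepsilon$ with targets
0.48/0.45/0.37/0.15 (hippocampus-, medial-temporal-, entorhinal- and
fusiform-like, the typical ordering of volumetric involvement).

What the phantom does **not** emulate: PET physics (scatter, attenuation,
tracer kinetics), realistic anatomy, site effects, or nonlinear
deformation. Passing recovery tests on the phantom therefore demonstrates
that the *method* recovers planted, disentangled, approximately
multiplicative regional effects under affine/gain/noise confounding — not
that it would achieve any particular correlation on clinical data.

## Preprocessing and splitting

Intensity normalization is two-step: divide by the volume's 99th
percentile, clip to $[0,1]$, then apply the monotone contrast map
$(1 - e^{-c v})/(1 - e^{-c})$ with $c = 3$ by default. The exponential form
was chosen because it fixes the endpoints 0 and 1, enhances mid-range
contrast, and reduces to the identity as $c \to 0$; the percentile is
per-volume (a cohort-level percentile is a drop-in alternative; the choice
is exposed as arguments). Values above the reference percentile clip to 1
so the MSE sees bounded inputs. Scans missing a required covariate are
excluded before training (`drop_missing()`), mirroring the usual practice
of requiring the guiding covariates.

Splitting is strictly subject-level: unique subject ids are shuffled with a
seeded RNG and assigned 65/15/20% to train/validation/test,
`floor` rounding for the first two blocks and the remainder to test —
deterministic and within one subject of the exact proportions. Every scan
of a subject lands in exactly one set, so longitudinal scans can never leak
across splits.

## Convergence diagnostics: phase diagrams

Two failure modes bracket the useful regime. With too much KL pressure the
posterior collapses: all $\mu_i$ converge to one point and the decoder
reproduces the cohort mean. With too little, the model behaves like a
deterministic autoencoder. The dispersion statistic
$D_\mu = \tfrac1N \sum_i \lVert \mu_i - \bar\mu \rVert_2$ over the
validation set quantifies this: `sweep_dispersion()` trains one unguided
model per $(d, \beta)$ cell at a shared reduced epoch budget and labels
cells *collapse* ($D_\mu < 0.05\times$ grid median), *degenerate*
($> 0.95\times$ grid maximum) or *stable*. The thresholds are exposed;
the source analyses identify regimes by visual inspection of the same
statistic, and any monotone labelling of the same surface would do.

`sweep_correlation()` is the second diagram: at fixed $d$, it trains one
guided model per $(\beta, \alpha_0)$ cell and records the *converged*
validation $|r(z_0, \text{score})|$ — the mean over the last three epochs,
which smooths batch noise. Small $\alpha$ leaves the latent uninformative
(near-zero regime, $|r| < 0.2$); large $\alpha$ drives $|r| \to 1$ by
sacrificing everything else (saturated regime, $|r| > 0.95$, a
non-informative optimum); between them lies the stable band from which the
default $\alpha = 2\times10^{-4}$ is taken. Grid values for a phase diagram
are chosen, as in any phase-diagram study, to span the regimes. The
packaged demonstration uses two scales. The dispersion diagram runs on a
16-cubed, 100-subject confounder-heavy phantom with a proportionally
reduced architecture ($\beta \in \{10^{-5}, 10^{-3}, 1\}$,
$d \in \{2, 8, 16\}$, 16 epochs per cell at a 3x learning rate so the
low-$\beta$ regime has time to spread); collapse at $\beta = 1$ is
architecture-independent physics and survives the reduction. The
correlation diagram cannot be reduced the same way — at 16-cubed
resolution the image simply does not determine the score well enough for
the saturated regime to exist at any $\alpha$ — so it runs on the full
32-cubed study cohort at a short shared budget (4 epochs per cell,
$\alpha \in \{0, 10^{-3}, 0.1\}$), where the three regimes appear
cleanly. Per-cell training failures are recorded and skipped, never fatal
to the sweep.

## Generative mapping and the voxel-wise GLM

To visualize what a guided dimension encodes, `average_reconstructions()`
decodes a grid of codes: the two guided dimensions are fixed at grid values
spanning their observed range on the test set (the central 95% interval, a
7x7 grid by default), while the remaining dimensions are sampled to
represent inter-subject variability, 64 samples per cell, and the decoded
volumes averaged — synthetic "mean scans" at controlled severity and age.
Two sampling details: (i) the free dimensions are drawn at the *empirical*
per-dimension standard deviations of the encoded latents (`free_sd =
latent_sds(...)` in the packaged pipeline) rather than at prior width —
with a weak KL weight the aggregated posterior is many times narrower than
$\mathcal{N}(0,1)$, and prior-width codes fall far outside the decoder's
trained range, drowning the guided-dimension response (prior-width
sampling remains the default form of the function, appropriate whenever
the aggregate posterior matches the prior); (ii) the same free-dimension
draws are reused in every grid cell (common random numbers), so the
Monte-Carlo error cancels almost entirely out of between-cell contrasts
such as the GLM slopes. The per-cell mean converges at the Monte-Carlo
$1/\sqrt{n}$ rate (tested); 64 samples put the sampling error well below
the planted effects.

`fit_voxelwise_glm()` then regresses cell-mean intensity on
$[1, z_0, z_1, z_0 z_1]$ at every voxel by ordinary least squares (one QR
decomposition for all voxels jointly). Grid values are treated as fixed
regressors — they are design points of the sampling scheme, not noisy
measurements — and are z-scored over cells by default so that
coefficient magnitudes are comparable across terms. The $\beta_0$ map
should localize the planted affected territory with the opposite sign to
the spared one; `roi_summary()` quantifies this against the ground-truth
masks, and `interaction_ratio()` — mean $|\gamma_{01}|$ over brain voxels
(intercept above 5% of its maximum) divided by the larger main-effect mean —
quantifies disentanglement: the generator is additive, so the fitted
interaction should be small. No voxel-wise significance testing is done;
the maps themselves are the output, deliberately unthresholded.

The GLM is fitted across grid cells only (not cells x samples): the model
of interest conditions on $(z_0, z_1)$, and the free-dimension sampling
variance is exactly what the per-cell averaging is there to remove.

## Classification and ablation

`classify_bootstrap()` quantifies the discriminative content of a feature
set: diagnosis is binarized (HC = 0, AD = 1; MCI and missing-diagnosis
scans are excluded — asserted by row accounting in the tests), a logistic
regression (iteration cap 1000) is fitted on bootstrap resamples of the
training rows and evaluated on the fixed test split, and accuracy,
sensitivity, specificity and balanced accuracy are reported as mean and sd
over 100 replicates. Resampling the training set against a fixed test set
is one of several bootstrap designs; it is the package's choice and is
configurable (the replicate count too — the source analyses report both 100
repetitions and a 10-resample variant). A single-class resample is redrawn
and counted. `per_dimension_report()` runs the same evaluation with each
latent dimension alone, exposing which dimension carries the disease
signal.

`run_ablation()` re-trains with all $\alpha_j = 0$ (a plain beta-VAE) under
the identical seed and split, and emits a paired comparison: held-out
latent-covariate correlations, GLM maps on matched reconstruction grids,
and z0-only classification. On the phantom, guidance is what concentrates
severity in $z_0$; without it the information spreads over dimensions and
the $z_0$-specific correlation drops substantially.

## Numerical choices and degenerate inputs

- Posterior heads are initialized at small scale (sd $10^{-2}$); the
  log-variance bias starts at $-2$ ($\sigma \approx 0.37$). With a weak
  KL weight the optimal posterior width is far below the prior's, and
  unit-width initial noise both drowns the similarity signal in
  reparameterization noise and attenuates the decoder's learned slopes
  (the classic errors-in-variables shrinkage); starting much narrower
  over-commits every dimension to reconstruction before the similarity
  terms can align them. All other layers use He initialization.
- Batch normalization uses batch statistics in training and running
  statistics (momentum 0.1) for all analysis-time encoding/decoding, so
  encoding is deterministic.
- A non-finite loss aborts training immediately, naming the first
  offending component.
- An all-zero volume cannot be normalized (explicit error); a planted
  effect large enough to drive intensities negative is clamped at zero and
  counted in the ground truth (`n_clamped`).
- Degenerate similarity batches (fewer than 2 complete pairs, zero
  variance) are skipped, not errors; degenerate GLM designs (collinear
  columns, too few cells) are errors naming the offending columns.
- Rank ties in the Spearman covariate use average ranks.

## Problem sizes

The packaged study conditions are a 300-subject, two-scans-per-subject
cohort of 32-cubed volumes — large enough that subject-level effects,
longitudinal structure and all confounders are present, small enough to
train on one CPU in minutes. Latent-covariate alignment plateaus near
epoch 10 under these conditions, but the decoder's *regional* response —
what the generative GLM maps measure — keeps sharpening to epoch 25
(reconstruction learns the template first, global factors next, regional
contrast last). The test suite therefore runs one guided arm at the full
25-epoch budget (the run all generative analyses use), the remaining
guided seeds at 10 epochs, and the unguided ablations at 6 epochs; the
acceptance script runs both arms at the full 25-epoch configuration.
Phase-diagram demonstrations use the scales described above.

## Known limitations

- The implementation is CPU-double-precision R/C++; it is meant for
  desk-scale experiments and method scrutiny, not for training on
  full-resolution clinical cohorts.
- Batch-level correlation with small batches is noisy; very small cohorts
  may need larger batches or more epochs for the similarity terms to act.
- The Spearman soft-rank temperature trades bias against gradient
  smoothness; the default has not been tuned beyond the desk scale.
- The phantom's realism limits are listed above; in particular the
  structural-volume covariates are construction-correlated with severity,
  so their alignment with $z_0$ is a consistency check, not biology.
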