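# synthmr

Cross-modality medical image translation in R: synthesize magnetic
resonance (MR) slices from aligned computed tomography (CT) slices with a
conditional generative adversarial network (GAN). MR contrast is often the
clinically informative one, but MR acquisition is slow and contraindicated
for some patients; when a co-registered CT slice exists, a learned CT→MR
mapping can stand in. `synthmr` provides the whole pipeline — networks,
objective, trainer, metrics, and a synthetic phantom generator with a known
ground-truth mapping so everything is testable without clinical data.

## The model

Two generators and two conditional patch discriminators:

* **G_MR** maps a CT slice to an MR slice; **G_CT** (the inverse
  generator) maps the synthesized MR back toward CT, constraining the
  forward mapping cycle-style. Both are residual encoder–decoders:
  7×7 conv → two stride-2 convs (64→128→256 channels) → nine residual
  blocks at H/4×W/4 → two fractional-stride convs → 7×7 conv, instance
  norm + ReLU everywhere except the final Tanh, so outputs live in
  [−1, 1]. Fully convolutional in any H, W divisible by 4.
* **D_MR, D_CT** score the channel-wise concatenation (condition,
  candidate) over overlapping patches, emitting a score grid (PatchGAN
  style, five convolutions).

Training minimises, over the generators,

```
L = L_GAN + λ_voxel · L_voxel + λ_perc · L_perc + λ_cos · L_cos
```

with defaults λ_voxel = 100, λ_perc = 1, λ_cos = 1: conditional
adversarial cross-entropy over patch grids; voxel-wise L1 for the MR and
reconstructed-CT pairs; perceptual L1 feature matching through a frozen
VGG16-topology extractor tapped at blocks 1–4, each layer scaled by
1/(H_j W_j C_j); and a von Mises–Fisher cosine re-identification loss,
`p(y = k | f(x)) = exp(κ ŵ_kᵀ f(x)) / Σ_c exp(κ ŵ_cᵀ f(x))`, treating
real-vs-generated discrimination as instance matching in embedding space.
Discriminators update every third iteration; the learning rate holds 2e−4
for the first half of training and decays linearly to zero.

Evaluation reports MAE, RMSE, PSNR = 10·log₁₀(MAX²/MSE) with MAX = 10 on
the package's fixed [0, 10] metric scale, SSIM (Gaussian-windowed, ≤ 1
with equality iff identical), and the Pearson correlation coefficient,
per image and in aggregate with 1.5·IQR box-plot summaries.

## A worked example

Train a small model on noiseless synthetic phantoms and evaluate it on
held-out pairs:

```r
library(synthmr)

cfg <- resolve_config(overrides = c(
  "phantom.side=32", "phantom.noise_sigma=0", "phantom.texture_amplitude=0",
  "generator.base_filters=16", "generator.n_residual_blocks=4",
  "discriminator.base_filters=16", "perceptual.width_mult=0.25",
  "training.epochs=10", "training.optimizer=adam",
  "training.lr_initial=2e-3", "training.seed=5"))

pc    <- do.call(phantom_config, cfg$phantom)
pairs <- lapply(generate_dataset(pc, 50), function(p)
  paired_sample(normalize(p$ct, "symmetric"),
                normalize(p$mr, "symmetric"), p$pair_id))
split <- split_dataset(pairs, 40, seed = 5)

fit <- fit_translation(split$train, training_schedule(
  epochs = 10, optimizer = "adam", lr_initial = 2e-3, seed = 5), cfg)

report <- evaluate_model(fit$g_mr, split$test)
glance(report)
```

On this run the report prints

```
# A tibble: 1 × 7
    mae  rmse  psnr  ssim   pcc n_pairs scale_max
  <dbl> <dbl> <dbl> <dbl> <dbl>   <int>     <dbl>
1 0.440 0.941  20.7 0.763 0.967      10        10
```

i.e. after 400 iterations the synthesized MR differs from the ground-truth
phantom MR by about 0.44 intensity units on the [0, 10] scale (the same
evaluation of the untrained network gives MAE ≈ 3.86), with SSIM ≈ 0.76
and pixel correlation ≈ 0.97 on held-out pairs. `tidy(fit)` returns the per-iteration loss
breakdown, `autoplot(report)` the metric box plots, and `run_ablation()`
repeats training under the `lgan` / `lgan+voxel` / `lgan+voxel+perc` /
`full` objective presets and tabulates the five metrics per preset.

A command-line wrapper (`inst/scripts/synthmr`) exposes the same pipeline
as `synthmr simulate | train | generate | evaluate | ablate` with a YAML
run configuration.

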