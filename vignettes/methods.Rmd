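---
title: "Cross-modality MR synthesis from CT: model, objective and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modality MR synthesis from CT: model, objective and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthmr)
```

## The problem

Magnetic resonance (MR) imaging carries rich soft-tissue contrast but is
slow, contraindicated for some patients, and requires an enclosed scanner;
computed tomography (CT) is fast and widely available. When an aligned CT
slice exists, a learned cross-modality mapping can synthesize the MR
appearance of the same anatomy. `synthmr` implements such a mapping as a
conditional generative adversarial network (GAN) with a cycle-style inverse
generator, trained on *paired*, co-registered CT/MR slices, plus the full
apparatus needed to exercise it end to end: image I/O, a synthetic phantom
generator with a known ground-truth mapping, a four-term objective, an
alternating training loop, and a five-metric paired-image evaluation suite.

## Model architecture

**Generators.** The forward generator `G_MR` (CT to MR) and the inverse
generator `G_CT` (synthesized MR back to CT) share one topology, a residual
encoder–decoder in the image-transformation-network family:

* a 7×7 stride-1 convolution to 64 channels (reflection padding),
* two 3×3 stride-2 convolutions to 128 then 256 channels (the encoder),
* nine residual blocks at the H/4 × W/4 bottleneck, each two 3×3 stride-1
  convolutions at 256 channels with reflection padding,
* two fractional-stride (transposed) 3×3 convolutions back to 128 then 64
  channels (the decoder),
* a final 7×7 stride-1 convolution to one channel.

Instance normalization and ReLU follow every convolution except the last,
which is followed by Tanh so outputs always lie in [−1, 1] — the package's
"symmetric" intensity domain. The network is fully convolutional: it
accepts any height/width divisible by 4 (the two stride-2 and two
upsampling stages) and preserves them, and its parameter count is
independent of the input size. `generator_audit()` captures every stage's
activation shape at run time for conformance checking.

Two decoder realisations are provided: transposed convolution (the
default, implemented as zero-interleaving followed by a stride-1
convolution, which is the exact adjoint construction) and
nearest-neighbour-upsample + convolution, a standard alternative that
avoids checkerboard artifacts.

**Discriminators.** `D_MR` and `D_CT` are conditional patch
discriminators: each consumes the channel-wise concatenation of a
condition image and a candidate image and emits a 2-D grid of patch
scores rather than a single scalar, so the adversarial signal acts on
local texture. The published description fixes five convolutional layers
with "normalization and non-linear processing" on layers 2–4 but not the
channel or kernel plan; we adopt the standard 70×70-receptive-field patch
plan (4×4 kernels; strides 2, 2, 2, 1, 1; widths 64–128–256–512–1),
instance normalization to match the generators, and leaky-ReLU slope 0.2.
Following the text literally, the first convolution has no
normalization/activation and the fifth emits raw scores. All of this is
configurable through `discriminator_spec()`.

**Initialisation.** All GAN weights are zero-mean Gaussian with σ = 0.02
(a common choice for this family; the source description is silent),
drawn from seeds derived from the run seed so builds are reproducible.

## The objective

Four terms, combined as
`total = adv + λ_voxel·voxel + λ_perc·perc + λ_cos·cos`
with defaults λ_voxel = 100, λ_perc = 1, λ_cos = 1 (`loss_weights()`).

**Adversarial.** Binary cross-entropy over the patch grids: `D_MR` pushes
the real pair (CT, MR) toward 1 and (CT, G_MR(CT)) toward 0; `D_CT` does
the same for the reconstruction (CT, G_CT(G_MR(CT))). The published
objective writes "1 − log D(·)" terms; we read these as the conventional
cross-entropy `log(1 − D(·))` — the literal expression is unbounded below
and inconsistent with the min–max game it is embedded in — and train the
generators with the standard non-saturating flip. The published real pair
for `D_CT` is (CT, MR) and is implemented that way by default;
`dct_real_pair = "reconstruction"` switches to the arguably intended
(CT, real-CT) pairing. Reported terms are means over the two
discriminator families, so a maximally uncertain discriminator scores
exactly 2·log 2. All logarithm arguments are clamped at 1e−7.

**Voxel-wise L1.** Mean absolute difference of the MR pair plus the CT
pair. We reduce by the *mean* over pixels (not the sum) so that
λ_voxel = 100 means the same thing at every resolution.

**Perceptual.** L1 feature matching through a frozen convolutional
extractor with the VGG16 topology, tapped at the post-activation ends of
blocks 1–4 (K = 4; configurable), each layer scaled by 1/(H_j·W_j·C_j)
and averaged over layers, summed over the MR and CT pairs. The package's
extractor uses *frozen random* weights (He-scaled, seed-reproducible)
rather than classification-pretrained ones: no pretrained weights ship
with the package, random multi-scale convolutional features are a
well-behaved perceptual metric (identical inputs map to identical
features; the loss is zero exactly on identity), and everything the loss
definition requires — frozen parameters, the scaling, the K-average — is
preserved. This is a deliberate design choice; users with a pretrained
backbone can obtain classification-grade features by swapping the
extractor's weights, and comparisons against pretrained-feature losses
are out of scope here.

**Cosine re-identification (vMF).** Real-versus-generated discrimination
is treated as object re-identification on the unit hypersphere: the
posterior over classes is the softmax of κ-scaled cosine similarities
between an embedding f(x) and unit class directions (a von Mises–Fisher
classifier; `vmf_head()`, `vmf_posterior()`, `cosine_loss()`). The source
leaves f(x), the class set and κ's sharing unspecified, so the package
fixes one defensible construction: f(x) is the L2-normalised spatially
pooled deepest perceptual tap; each real image defines its own class
direction w = f(real); the negative classes are a FIFO buffer of the most
recent real-image features (default 16 per modality), so C = 1 + #buffer;
κ (default 16) is shared across classes and modalities. With an empty
buffer C = 1 and −log 1 = 0, so the term is skipped until at least one
negative exists. The paired loss sums the (MR, generated MR) and
(CT, reconstructed CT) terms.

## Training

`fit_translation()` runs the alternating optimisation: each iteration
draws one pair (mini-batch of one, reshuffled every epoch from the run
seed), the discriminators are updated on every third iteration (1-based
`i %% 3 == 0`, so ⌊n/3⌋ of n steps; the period is configurable), and both
generators are updated every iteration from the weighted objective. The
default optimizer is plain mini-batch SGD, honouring the published
training description; Adam (β₁ = 0.5) is available in the configuration
and is what the package's own small-scale experiments use, since plain
SGD at learning rate 2e−4 converges far too slowly at desk scale. The
learning rate holds its initial value (default 2e−4) for the first half
of the total iterations and then decays linearly to exactly zero at the
final iteration; at the study scale of 257 training pairs × 100 epochs
that is 12,850 constant + 12,850 decaying iterations. Iteration positions
are 1-based throughout, which makes the constant/decay boundary and the
final-iteration zero exact.

Checkpoints (all four networks, optimizer states, feature buffers,
iteration counter) are written every epoch; loading one and continuing
reproduces an unbroken run bit for bit, because the only randomness —
initialisation and epoch shuffling — is derived deterministically from
the run seed.

## The phantom generator

Real paired CT/MR brain data cannot ship with the package, so
`phantom_config()` / `generate_pair()` synthesize co-registered pairs
with a *known* cross-modal mapping: one tissue-label field per pair (a
background, a large central "head" ellipse, and random rotated ellipses,
later shapes overwriting earlier ones), per-tissue CT and MR mean
intensities, a smooth low-frequency sinusoidal texture field drawn
independently per modality, and i.i.d. Gaussian noise. Defaults (side
256, 4 tissues, 6 shapes, texture amplitude 0.05, noise σ 0.02) give
images with tissue contrast, smooth intra-tissue structure for the
perceptual loss to match, and mild noise — chosen once as a plausible
stand-in for resized brain slices. Because distinct tissues have distinct
CT levels, the noiseless mapping is an exact per-tissue lookup
(`phantom_oracle()`), which is the ground truth that scaled-down training
runs are scored against. Pair *i* draws from a counter-based stream
derived from (seed, *i*), never from global RNG state.

What the phantoms deliberately do not model: CT/MR physics (Hounsfield
units, MR sequences), anatomical realism, registration error, scanner
artifacts. Passing tests on phantoms therefore demonstrates that the
optimisation machinery learns an identifiable cross-modal mapping under
controlled conditions — not clinical image quality.

## Evaluation

`evaluate_model()` computes, per test pair and in aggregate: MAE, RMSE,
PSNR = 10·log₁₀(MAX²/MSE), SSIM and the Pearson correlation coefficient,
between the real MR and `G_MR(CT)`. Metrics are computed after an affine
map of both images onto a fixed [0, 10] scale so that the PSNR peak value
MAX = 10 is literally the maximum pixel value; the scale is recorded in
the report and configurable. The published SSIM formula omits the
covariance term of the standard statistic and appears typographically
corrupted; the package implements the standard windowed SSIM (Gaussian
11×11 window, σ = 1.5, stabilisers (0.01·L)² and (0.03·L)²), which
satisfies the constraints the source does state: SSIM ≤ 1 with equality
iff the images are identical. Likewise the printed correlation
denominator duplicates its σ factors; the standard Pearson coefficient —
the quantity named — is implemented. Identical images yield PSNR = +∞,
which is reported per image but excluded (and counted) in the aggregate
mean. Box-plot summaries use quartiles with whiskers
[Q25 − 1.5·IQR, Q75 + 1.5·IQR]; points outside are flagged as outliers.

## Numerical and design notes

* Reflection padding uses mirror-without-edge-repeat indexing; its
  gradient folds padded contributions back onto the mirrored interior
  positions, verified against finite differences along with every other
  layer type.
* The L1 subgradient at exactly zero difference is 0 (the `sign`
  convention).
* `normalize()` maps raw images by per-image min–max (scanner ranges
  differ; this makes phantoms and external data uniform), fixed-interval
  domains affinely; constant images map to the interval midpoint. PNG
  files are written 8-bit (the available encoder's limit) with NIfTI as
  the lossless interchange; manifest loading treats PNG's [0, 1] code
  range as the unit domain so intensities stay comparable across pairs.
* Resizing is bilinear with pixel-centre alignment, straight to the
  target square (no aspect preservation), matching the dataset
  convention of resizing all samples to one square resolution.
* Ablation presets `lgan`, `lgan+voxel`, `lgan+voxel+perc`, `full` mask
  the loss weights cumulatively; `run_ablation()` trains each under an
  identical seed and schedule and tabulates the five metrics per preset.

## Test and experiment scale

The package's correctness tests use deliberately small problems: 8–32 px
images (24 px is the smallest side the five-convolution patch plan
supports end to end), 8–16 base filters, 2–4 residual blocks, a
width-0.25 or -0.125 perceptual extractor, and tens to hundreds of
iterations. The learning
check trains on 40 noiseless 32×32 phantom pairs for 400 iterations
(Adam, 2e−3) and asserts a ≥ 5× reduction of held-out MAE against the
phantom ground truth plus the full-objective preset beating the
adversarial-only preset; these sizes are the package's own choice of a
desk-scale experiment in which the mapping is identifiable and
convergence is expected. Architecture conformance is audited at the full
256×256 / 64-filter / 9-block plan. Full-scale training (25,700
iterations at 256×256) is a GPU-class undertaking and is intentionally
not part of the test suite.

## Known limitations

* Mini-batches are fixed at one pair (the study design); there is no
  multi-batch or multi-GPU path.
* The perceptual extractor's random features are a proxy for pretrained
  semantic features; absolute perceptual-loss values are not comparable
  to pretrained-backbone implementations.
* The re-identification construction is one defensible reading of an
  under-specified loss; alternatives (discriminator features, a
  dedicated encoder) are not implemented.
* DICOM ingestion, 3-D volumetric training and image registration are
  out of scope; inputs are assumed pre-aligned single-channel slices.
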