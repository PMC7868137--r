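---
title: "Mask-attention adversarial inpainting of tumors in CT slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mask-attention adversarial inpainting of tumors in CT slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctinpaint)
```

## The problem and the model

Deep models for lesion segmentation and computer-aided diagnosis are starved
for abnormal training images: tumor-bearing CT slices are rare, private, and
expensive to label. `ctinpaint` synthesizes tumor-bearing liver-CT-like
slices by *inpainting*: every tumor pixel of a labeled slice is set to the
white value 4096 (the top of the 12-bit raw range), producing what we call
the **attention map** — the image itself, with the regions to be synthesized
whitened. A conditional generator learns to fill those regions with
plausible lesion gray values and texture; once trained, whitened regions can
be stamped onto *healthy* slices at arbitrary positions and the generator
turns them into tumors.

Training is adversarial. The generator `G` consumes the (standardized)
image and attention map and emits a synthesized slice. A patch
discriminator `D` sees two pairings of image and attention map: pairing A
couples the real image with the attention map, pairing B the synthesized
image with the same attention map, and it scores each as a grid of
real/fake probabilities. The objectives are

* generator reconstruction: `L_G = E ‖ r − G(v) ‖₁` (mean absolute error
  between the real slice `r` and the synthesis, on standardized
  intensities),
* discriminator: `L_D = E log D(real pairing) + E log(1 − D(fake pairing))`,
  averaged over the probability-map entries and maximized by `D`,
* combined: `L = λ₁ L_G + λ₂ L_D` with `λ₁ = 100`, `λ₂ = 1`.

The heavy reconstruction weight makes the adversarial term a texture prior
rather than the main signal, the usual conditional-GAN regime. Because the
printed generator objective is a pure reconstruction term, the generator
step here adds the standard non-saturating adversarial feedback
`−λ₂ E log D(fake)`; setting `reconstruction_only = TRUE` in `training_config()`
trains the generator on the L1 term alone.

## Architecture

**Generator** (`generator_config()`, `build_generator()`): a U-shaped
network with *two* weight-independent contracting paths — one fed the image,
one the attention map — and one expansive path. Each contracting block is
pre-activation (ReLU → convolution → batch normalization) with kernel 4,
stride 2, so the side halves per block; at the canonical 512×512 input,
nine blocks reach a 1×1 bottleneck with 1024 channels (schedule
64, 128, …, capped at 1024). The first four blocks use dilation 2
(effective kernel 7, padding 3 — still exactly halving) to enlarge the
receptive field while the maps are still larger than 32×32; beyond that
scale regular convolutions take over. The two bottlenecks are concatenated
and fused by a 1×1 convolution. Expansive blocks are transposed
convolutions (kernel 4, stride 2) with batch normalization, dropout in the
three coarsest blocks, and a residual skip from the encoders at every scale
except the output.

**Mask-attention fusion** (`project_features()`, `similarity()`,
`attention_distribution()`, `apply_attention()`): at coarse decoder scales
the two encoder streams are fused by attention rather than plain addition.
1×1 projections produce query/key maps `A` (image path) and `B`
(attention-map path); `S[i, j] = ⟨A_i, B_j⟩` couples all positions; a
numerically stabilized softmax over `i` makes each column of `D` a
probability distribution; the output at position `j` is the `D`-weighted sum
of a value projection `V` of the image-path features, added residually to
the decoder stream. Design choices the source description leaves open, and
how we resolved them: the softmax axis follows the printed denominator
(sum over `i`, so `D` is column-stochastic); `j` is read as a flattened
spatial position; a value projection is introduced because aggregation
needs one (standard attention form); the attended output is *added* to the
decoder stream ("transferred via residual connections") rather than
replacing it. The quadratic cost of `N × N` similarity restricts fusion to
scales with few positions: side ≤ 32 canonically (N ≤ 1024); finer scales
use plain additive skips from both encoders.

**Discriminator** (`discriminator_config()`, `build_discriminator()`): six
blocks consuming the channel-concatenated pairing — four of kernel 4 /
stride 2 / padding 1 (channels 64, 128, 256, 512), then two of kernel 4 /
stride 1 / padding 1 (512, then 1, sigmoid). On a 512×512 pairing this
emits a 30×30 probability map — 900 overlapping patches, each unit's
receptive field 142×142 pixels (`receptive_field()` implements the
standard recursion `rf ← rf + (k_eff − 1)·jump`, `jump ← jump·stride`). This
geometry is the unique standard patch-discriminator shape reproducing all
three printed numbers from a 512 input. Block composition follows the
listed order (convolution, ReLU, batch normalization), with batch
normalization omitted in the first and last blocks. The scalar verdict is
the arithmetic mean of the map.

## Inputs, normalization, and file formats

Raw slices live in `[0, 4096]` (a 12-bit CT convention; the white marker
4096 is stored literally even though a 12-bit range tops out at 4095, and
is clamped only on export). `normalize_slice()` standardizes each slice to
zero mean, unit variance, using the *population* standard deviation
(divide by `n`) and per-slice statistics — the transform is presented
alongside per-image processing, so per-slice is the natural reading; the
statistics are retained for exact inversion. The attention-map input is
standardized with its source slice's statistics so the white marker stays
maximal. At inference from a whitened slice alone (`synthesize()`), the
whitened image's own statistics are used, inverted, and the result clamped
to `[0, 4096]`.

Lossless integer round trips use 16-bit TIFF (the default writer) or
NIfTI; PNG is read at 8 or 16 bits — 8-bit input is mapped by the fixed
factor 4096/255 — and written at 8 bits, the installed PNG writer's only
mode.

## The phantom generator

`phantom_spec()` / `generate_phantom()` produce the desk-scale stand-in for
a real CT dataset: a randomly placed elliptical "organ" whose texture is
band-limited (Gaussian-smoothed white) noise over a base level drawn from
the central half of `organ_intensity_band` (default 1000–1400, emulating
contrast-enhanced parenchyma on an offset 12-bit scale), on a darker
background (default 150). Lesions are compact blobs — a radius modulated by
low-order harmonics — placed strictly inside the organ, non-overlapping,
with a −250 intensity offset (hypodense, the common contrast-CT
appearance) and finer-grained texture, together with their binary mask.
Texture is zero-centered over the organ so the organ mean provably lies in
the configured band. Placement that cannot succeed raises
`infeasible_spec` rather than degrading. Dataset items derive per-item
seeds from a master seed by a counter scheme, so item `i` is independent
of generation order.

What the phantoms do *not* emulate: anatomy (no ribs, vessels, or
neighboring organs), partial-volume boundaries, scanner noise spectra, or
the intensity statistics of real contrast CT. Tests passing on phantoms
demonstrate that the machinery — shapes, gradients, convergence,
determinism — is correct at desk scale; they say nothing about perceptual
quality on clinical data, which requires the real dataset and GPU-scale
training.

## Training procedure and hyperparameters

`training_config()` defaults are the published set: learning rate 2·10⁻⁴,
Adam first-moment coefficient 0.5 (second moment 0.999, the usual default,
as only the first is published), λ₁ = 100, λ₂ = 1, exponential decay 0.99
applied to the learning rate once per epoch (the most common reading of an
unattributed decay constant), batch size 1, 10 epochs, dropout 0.5, losses
logged every 100 iterations, checkpoints every 500. Batch size 1 makes
batch normalization per-sample; running averages serve evaluation mode.
Each iteration takes one discriminator step (ascending the patch log loss,
entries clipped to `[10⁻⁷, 1 − 10⁻⁷]`) then one generator step. Training
is fully seeded: initialization, data order, and dropout all derive from
`training_config(seed)`, and two runs with identical configurations
produce identical loss records.

During training both encoder paths receive the *whitened* image — the
inference-time situation, where the intact original does not exist inside
the masked region; feeding the intact original to the image path (a
defensible alternative reading, under which reconstruction is trivial) is
available via `reconstruction_only = TRUE`.

Up-convolutions are transposed convolutions, which produce the well-known
checkerboard artifact early in training; it fades as training proceeds and
no resize-convolution substitution is made.

## Desk-scale configurations and problem sizes

The package's own benchmark sizes, chosen so a laptop-class CPU runs them
in minutes: `toy_generator_config(64)` (depth 6, channels 16–128,
attention fusion at sides ≤ 16) and `toy_discriminator_config(64)` (same
six-block geometry as canonical — hence the same 142-pixel receptive
field — with channels 16–128). The overfit benchmark trains 500 updates on
a single phantom (replicated 50-fold so 10 epochs of the published
schedule equal 500 updates, keeping the per-epoch decay meaningful); it
reduces evaluation-mode reconstruction L1 more than tenfold from
initialization. The inpainting benchmark trains 10 epochs over 100–200
phantoms (1000–2000 updates) and scores masked-region PSNR on held-out
phantoms against the white-filled input as baseline. The canonical 512
configuration is exercised forward-only (architecture arithmetic).

## Numerical choices

* Weight initialization: Gaussian, standard deviation 0.02 (the customary
  conditional-GAN scale); batch-norm gain 1 ± 0.02.
* Softmax: stabilized by per-column maximum subtraction; exact
  column-stochasticity to 10⁻⁶ is tested over random matrices.
* Batch normalization: ε = 10⁻⁵, momentum 0.1; omitted at the 1×1
  bottleneck, where a single spatial position has no variance.
* L1 gradient: the subgradient `sign(x)/n`; ties at exactly zero get 0.
* Log-loss clipping at ε = 10⁻⁷ with zero gradient in the clipped region.
* PSNR: `10·log₁₀(range²/MSE)` with default range 4095; identical images
  return `Inf`, and dataset summaries exclude infinite values with a
  reported count. An optional mask restricts scoring to whitened regions.
* Patch transforms: right-angle rotations are exact grid permutations (so
  the dihedral group is reproduced bit-exactly); other angles use bilinear
  resampling for pixels and nearest-neighbour for masks, re-binarized at
  0.5. Scale factors default to `[0.75, 1.25]`, keeping lesions at
  plausible extents; rotation angles are continuous in `[0°, 360°)`, the
  unqualified reading that maximizes diversity.

## Known limitations

* No DICOM input, no 3D synthesis, no Hounsfield windowing presets.
* The adversarial runs here are desk-scale; the published full-scale
  quality numbers require the external CT dataset and GPU training, which
  this package does not attempt to reproduce.
* The quadratic attention cost caps fusion at coarse scales; finer scales
  fall back to additive skips.
* Single-threaded determinism is guaranteed; multi-threaded BLAS may
  reorder floating-point reductions.
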