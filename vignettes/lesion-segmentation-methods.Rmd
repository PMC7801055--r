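---
title: "Methods: feature-fusion U-Net segmentation of diabetic retinopathy lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature-fusion U-Net segmentation of diabetic retinopathy lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Diabetic retinopathy screening rests on finding four lesion types in color
fundus photographs: microaneurysms (MA, tiny dark capillary dilations of a
few pixels), hard exudates (EX, bright sharply demarcated lipid deposits),
soft exudates (SE, pale fluffy cotton-wool spots) and hemorrhages (HE, dark
irregular blood leaks). Pixel-wise segmentation of these lesions is hard for
two reasons: the lesions occupy a tiny fraction of the image (often well
under 1% of pixels), and their spatial scales differ by an order of
magnitude. `fundusseg` implements an encoder-decoder convolutional network
specialized for this regime, together with the full tile-based
preprocessing and reconstruction pipeline around it.

## The network

The model is a U-Net-shaped encoder-decoder with three departures from the
classical design.

**Convolutional downsampling.** Every resolution change in the encoder is a
learned 3×3 convolution with stride 2; there is no pooling operator
anywhere in the network. Pooling discards spatial detail that tiny lesions
cannot afford to lose, and a learned strided kernel additionally mixes
information across channels.

**MSFF encoder blocks.** Each encoder stage is a multiscale feature-fusion
block: a 3×3 dilated convolution (dilation 2 by default) widens the
receptive field at constant resolution, and is followed by three channel
*splitting* steps. Step *k* takes its *C_k* input channels, retains
⌊*C_k*/3⌋ of them through a 3×3 convolution, and passes the remaining
*C_k* − ⌊*C_k*/3⌋ on through a 5×5 convolution. After three steps the three
retained groups and the final pass-on group are concatenated — by
construction their widths telescope back to exactly the entry width — and a
1×1 convolution maps to the block's output width, to which an identity
residual (1×1-projected on channel mismatch) is added. The floor-thirds
reading of "keep 1/3 of the channels per step" is the one under which the
concatenation width is conserved exactly, which we verify as an invariant
(`msff_split_widths()`).

**CCA decoder fusion.** Where a classical U-Net concatenates the upsampled
decoder map LD with the skip connection SK, each decoder stage here first
computes a shared contextual channel attention: both maps (LD bilinearly
upsampled and 1×1-projected to SK's width *c*) are globally average-pooled
to *c*-vectors, squeezed by a 1×1 convolution with batch normalization to
*c/r* channels (*r* = 2), passed through an RReLU and expanded back to *c*;
the two vectors are added and gated. The gate rescales *both*
full-resolution maps channel-wise before concatenation, so decoder and skip
features share one attention. The gate activation is the RReLU itself, as
the defining equation of the module prescribes — an unbounded gate is
unusual (squeeze-excitation practice uses a sigmoid), and we expose
`gate = "sigmoid"` as an ablation, but the default follows the published
operator chain exactly. Likewise the pooling is applied after upsampling,
per the printed operator order, although average pooling makes the order
nearly immaterial.

All activations are randomized leaky rectifiers (RReLU): during training
the negative slope is drawn per element from U(1/8, 1/3) — the standard
interval from the activation literature — and at evaluation the
deterministic midpoint slope is used, making inference reproducible.
Weights are He-initialized (variance 2/fan_in), the natural scheme for
rectifier networks; the initializer's defining variance is checked
statistically in the test suite.

A 3×3 stem convolution lifts the 3-channel input to the base width before
the first MSFF block, since the splitting cascade needs at least 9 channels
to retain a nonzero group at every step.

**Open architecture parameters.** The source description leaves the depth
and per-stage widths open (and the ~1M parameter count reported for the
original cannot be reconstructed from them). We default to depth 4 and base
width 16, doubling per stage; both are configurable
(`ffunet_config()`), and tests use depth 1–2 with base width 9–12 so the
whole suite runs in minutes on one CPU. One binary output head is trained
per lesion class (the published evaluation reports each class separately);
a multi-label head is available via `out_classes`.

Because no deep-learning framework is available to R here, the network,
its backward pass and the Adam optimizer are implemented in the package
itself, with im2col convolution kernels in C++ (RcppArmadillo). The
backward pass is verified against central finite differences of the full
network loss in both evaluation and training modes (relative error ~1e-7),
which is the strongest correctness evidence a hand-derived gradient can
offer.

## The Balanced Focal Loss

With lesion pixels outnumbered ~100:1, plain cross-entropy converges to
"predict background". The training loss is, per pixel, with natural
logarithms,

    L_i = w · | y_i − Q_i^γ | · ( −[ (1 − y_i) log(1 − Q_i) + y_i log Q_i ] )

where *Q_i* is the predicted probability, *y_i* the binary label, γ = 2 the
focusing exponent and *w* the class-weight fraction — the ratio of lesion
pixels to all pixels in the training masks (`estimate_class_weight()`, or a
fixed value). For a positive pixel the modulating factor 1 − *Q*^γ vanishes
as *Q* → 1, quieting well-classified lesion pixels, but decays much more
slowly than the standard focal factor (1 − *Q*)^γ: at *Q* = 0.9, w = 0.1
the loss is 0.0020 — five times below weighted cross-entropy (0.0105) —
while the α-balanced focal loss is a hundred times below it (0.000105). At
*Q* = 0.1 the loss (0.228) is essentially the full weighted cross-entropy
(0.230). Misclassified pixels therefore keep nearly their full gradient
while easy ones are damped only moderately. The absolute value guarantees
nonnegativity for both label values.

Numerical choices: probabilities are clamped to [ε, 1−ε] with ε = 1e-7
before any logarithm, and the network's sigmoid output is clamped the same
way, so the loss and its analytic gradient are finite everywhere. The
reduction defaults to the per-pixel mean (the defining sum only rescales
the learning rate); both are available.

## Preprocessing

Steps, in order, on 0..255 RGB images (`preprocess_fundus()`):

1. **ROI cropping** — Otsu's threshold on the luminance channel, largest
   8-connected above-threshold component, tight bounding box. The channel
   and connectivity are our choices (the operators themselves are standard
   for fundus field-of-view extraction); EBImage's 4-connected labeller was
   not used for the component step, which is 8-connected in C++ here.
2. **Gaussian denoising** — 3×3 kernel, σ = 0.8 (a standard σ for a 3-tap
   Gaussian; configurable), edge-replicating boundary.
3. **CLAHE** — contrast-limited adaptive histogram equalization on the L
   channel of LAB (clip limit 2, 8×8 tile grid, common fundus practice;
   configurable), chroma untouched.
4. **Normalization** — (x − μ)/θ per channel with μ, θ pooled over the
   *training* images only, reused verbatim at test time to avoid test-set
   leakage.
5. **Augmentation** — paired horizontal flips (p = 0.5), rotation ±15°,
   shift ±10%, rescale 0.9–1.1; the mask is resampled nearest-neighbour so
   it stays binary. The ranges are unpublished; these defaults are ordinary
   for fundus augmentation and recorded in the function signature.

Denoising follows cropping; the published enumeration lists the steps in
this order without fixing it explicitly, and the two orders differ only in
a 1-pixel boundary band.

## Tiling and reconstruction

Full fundus photographs (4288×2848 for the reference camera) are diced into
256×256 windows at stride 64 (`dice_image()`); offsets enumerate all stride
multiples plus a final edge-flush offset per axis so every pixel is
covered. Tiles whose field-of-view coverage is below 0.5 (our default; no
published value) are eliminated as background. At inference the per-tile
sigmoid *probabilities* are averaged over every window covering a pixel —
16 for interior pixels at the default geometry, 1–15 near edges — and
thresholded at 0.5 afterwards; averaging probabilities rather than hard
labels is the information-preserving reading of "averaging the segmentation
results", and the threshold is configurable. Pixels covered by no valid
tile are reported `NA`, never silently 0. Dicing operates on the cropped
ROI image. Coordinates are 0-based and half-open throughout the tiling
bookkeeping.

## Training

Adam (β₁ = 0.9, β₂ = 0.999), initial learning rate 2e-3 (the published
schedule's "2 × 10³" read as 2×10⁻³ — the positive exponent is an evident
typo since a rate of 2000 diverges), divided by 10 whenever the validation
loss fails to improve for 5 consecutive epochs (the division factor is
published, the patience is ours), 100 epochs and batch 64 by default.
Batches draw positive and negative tiles 1:1 when both exist; 20% of tiles,
stratified by lesion presence, form the validation split; the
best-validation parameters are restored at the end. A fixed seed fixes
initialization, data order and augmentation draws exactly (the BLAS is
deterministic here, so in practice whole runs reproduce bit-identically).

## The synthetic generator

`generate_fundus()` emulates exactly the structure the pipeline relies on:
a bright disc (field of view) on a black border so ROI detection has a
target; curvilinear dark vessel-like tracks so denoising and contrast
enhancement act on realistic clutter; Gaussian pixel noise (σ = 5 by
default) added *after* lesion stamping so the denoiser has work to do; and
lesions stamped as anti-aliased discs (ellipses for HE) with
class-appropriate sign and scale — MA: radius 1.5–3 px, dark; EX: 8–20 px,
bright; SE: 10–24 px, bright with a wide soft edge; HE: 8–24 px elliptical,
dark. Counts per image default to 10–25 (MA), 3–8 (EX), 2–5 (SE), 2–6
(HE). Masks are exact: a pixel is positive iff its (elliptical) distance to
a lesion centre is at most the stamped radius, and the generator returns
the lesion table so tests can recount masks independently. Everything is
deterministic in the configuration seed.

What it does **not** emulate: optic disc and fovea anatomy, vessel
branching topology, illumination fields, camera optics, JPEG artifacts, or
the texture of real lesions. Passing tests on synthetic data therefore
demonstrate that the pipeline's machinery — geometry, bookkeeping, losses,
optimization — is correct, not that the trained weights transfer to
clinical images; training on real annotated fundus data remains necessary
for clinical performance figures.

## Problem sizes used in the tests

The test suite trains depth-1/depth-2 models with base width 9–12 on 64×64
synthetic tiles: an overfitting check (8 tiles, 200 epochs, training DICE
above 0.8) and an end-to-end smoke test (synthetic dataset → preprocess →
short training → whole-image prediction → evaluation). These sizes were
chosen so the full suite completes in a few minutes on a single CPU while
still exercising every code path; they are deliberately far below the
published experiments' scale, whose benchmark scores on the clinical
dataset are out of scope here (they require the original images and
GPU-scale training).

## Known limitations

- The hand-rolled network is CPU-bound R/C++; it is meant for method study
  and moderate images, not high-throughput clinical inference.
- The RReLU gate in the CCA module is unbounded; with He-initialized
  weights the head logits can saturate the sigmoid early in training (the
  clamp keeps gradients finite). The sigmoid-gate ablation avoids this at
  the cost of departing from the defining equation.
- Per-image (macro) metric averaging is available, but the default
  micro-average follows the count-based metric definitions.
- Checkpoints are RDS files; they embed the architecture configuration but
  are not portable to other frameworks.
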