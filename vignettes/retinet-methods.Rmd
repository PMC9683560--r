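---
title: "retinet: models, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{retinet: models, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why
each open design point was resolved the way it was. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The two networks

**CSP_UNet** segments retinal vessels per pixel. Its encoder is a stem
(3×3 stride-1 convolution, then 3×3 stride-2) followed by three stages
of a cross-stage-partial (CSP) bottleneck block plus a stride-2
convolution, for a total downsampling of ×16. A CSP block splits its
output width in half: one path applies a 1×1 projection and `repeats`
residual bottlenecks (1×1 then 3×3 convolution with an additive skip),
the other is a plain 1×1 shortcut; the two halves are concatenated,
normalised, and fused by a final 1×1 convolution. The decoder consists
of four modules, each applying atrous spatial pyramid pooling (ASPP — a
1×1 branch plus three 3×3 dilated branches at rates 6/12/18, padding
equal to dilation so shape is preserved, concatenated and projected
back) followed by bilinear ×2 upsampling and a convolution block. A
final 3×3 convolution and sigmoid produce the probability map, which is
binarized at 0.5.

**MTNet** shares the CSP_UNet encoder bitwise between two heads (hard
parameter sharing). Branch I (grading) applies a stride-2 convolution
block and two further convolution blocks at 1/32 resolution, global
average pooling, and a fully-connected layer to 5 logits, normalised by
softmax. Branch II is the CSP_UNet decoder. One forward pass yields
both the 5-class grade distribution and the full-resolution vessel
probability map.

Every convolution is followed by batch normalisation and LeakyReLU
(negative slope 0.1) and therefore carries no bias; only the final
output convolutions (1-channel segmentation head) keep a bias and skip
normalisation.

Decisions taken where the architecture family leaves details open:

- *Decoder module 1 has no skip concatenation.* Skips exist at 1/2,
  1/4 and 1/8 resolution (the three CSP stage outputs); at 1/16 the
  only tensor is the encoder output itself, so the deepest decoder
  module runs ASPP directly on it and modules 2–4 concatenate the
  matching skips.
- *Branch I uses softmax*, the standard closure for a 5-way exclusive
  grade; a per-class sigmoid would not yield a distribution. Branch I
  also pools globally before the FC layer — flattening a 32×32×C map
  would multiply the head's parameter count far past its printed
  budget (Section 2).
- *LeakyReLU slope 0.1*, *bilinear upsampling with half-pixel centres
  (no corner alignment)*, *3×3 convolutions with padding 1*, *Kaiming
  fan-in initialisation* matched to the LeakyReLU gain, under a
  recorded seed. All are the common defaults of this model family and
  are fixed here for reproducibility.

## 2. Width calibration against the printed complexity budgets

The architecture family is quantitatively pinned only by its published
complexity figures: 15.1 M parameters / 46.0 GFLOPs for the
segmentation network at 512² input, 18.8 M / 24.9 G for the
grading-only network, 24.8 M / 48.5 G for the joint network, and the
statement that sharing saves 26.8 % parameters and 31.6 % computation.
Subtracting the three totals gives per-component budgets — encoder
9.1 M / 22.4 G, decoder 6.0 M / 23.6 G, classification head 9.7 M /
2.5 G — and those six numbers were used as calibration constraints: an
integer search over stage widths and CSP repeat counts (closed-form
costs cross-checked against the package's own accountant) selected

```
widths   32 / 64 / 448 / 1328       (encoder stages)
repeats   1 /  2 /  6               (CSP bottlenecks per stage)
decoder  ASPP widths 71 / 193 / 32 / 24, upsample widths 78 / 68 / 31 / 16
head     conv widths 224 / 528 / 1252
```

(the exact values live in `ret_default_hyper()`), which reproduce all
printed totals at one decimal. The head's MAC/parameter ratio forces
its convolutions to 1/32 resolution: at 512² input a parameter at 16²
output pixels costs 256 MACs, so 9.7 M parameters ≈ 2.5 GFLOPs, exactly
the printed pair.

One constraint cannot be met: the published 12.1 GFLOPs at 256² input.
The segmentation network is fully convolutional, so **every**
per-output-pixel MAC count scales exactly ×4 from 256² to 512²; 46.0 at
512² forces 11.5 at 256², under any profiler convention. The package
reports the honestly computed 11.5. Relatedly, "GFLOPs" is interpreted
as giga-MACs (1 MAC = 1 reported FLOP, the dominant profiler
convention) and "Parameters (MB)" as millions of parameters — the
classic U-Net's ≈34.5 M parameters match the published 34.5 under that
reading, while its float32 size (≈138 MB) does not. The convention is
one global knob (`flops_per_mac`).

Parameter counting rules: convolution `k²·Cin·Cout` (+`Cout` if
biased), batch norm `2·Cout` (scale and shift; running statistics are
buffers, not parameters), FC `Nin·Nout + Nout`. Zero-MAC ops:
activations, batch norm (inference-folded), bilinear upsampling,
pooling, softmax. `count_params()` is validated against brute-force
enumeration of every allocated weight array (`ret_num_params()`) — the
two must agree exactly, on the tiny and the full calibrated spec.

## 3. Losses and metrics

Segmentation uses per-pixel **binary** cross-entropy against the
sigmoid output — not a 2-way softmax — because the inference path is a
single-channel sigmoid thresholded at 0.5; plus **soft Dice**
`1 − (2Σpy + s)/(Σp + Σy + s)` with smoothing `s = 1` on raw
probabilities (differentiable, and the empty–empty case is 0 rather
than undefined). Probabilities are clipped to `[1e-7, 1 − 1e-7]` before
logarithms. The deep-supervision generalisation
`Σ_k λ_k (ce_k + dice_k)` is implemented with default `n = 1, λ = 1`
(no deep supervision; values of `n` and `λ` are otherwise unstated in
this model family). Grading uses categorical cross-entropy
`−log p_label`; the joint loss is the plain sum of the two branch
losses, kept as a breakdown for logging.

Metrics are confusion-count based. Decisions:

- *Pooling.* Dataset metrics sum TP/FP/TN/FN over all images, then
  apply the formulas once. This matches reporting a single number per
  dataset and preserves the algebraic identity `F1 = 2·IoU/(1+IoU)`,
  which the tests exercise including on counts that print the
  (IoU 0.6674, F1 0.8006) pair. Per-image averaging is available as an
  option but breaks the identity.
- *Tie rule.* Probability exactly 0.5 maps to vessel (`>=`); fixed so
  binarization is bit-exact.
- *0/0 ratios* (e.g. empty prediction and empty truth) are defined as 0
  and flagged with a warning, keeping dataset pooling total.
- *No field-of-view masking by default* — all pixels count; an optional
  `fov` argument restricts counting when a FOV mask exists.

Published precision/recall columns in this model family are mutually
inconsistent with their printed F1 under the standard formulas; this
implementation follows the formulas literally and does not attempt to
reproduce those columns.

## 4. Training protocol

Settings: Adam (β₁ 0.9, β₂ 0.999, ε 1e-8, no weight decay — framework
defaults, otherwise unstated), initial LR 1e-3 cosine-annealed to 2e-7,
batch size 4, 60 epochs per stage. The cosine schedule is stepped per
epoch (60 schedule points), matching the epoch-wise framing of the
protocol. Checkpoint selection keeps the minimum monitored loss, ties
to the earliest epoch.

Stages: (1) grading data only — branch I and the shared encoder update;
(2) vessel data only — branch II and the encoder update; (3) joint —
each optimisation step draws one grading batch and then one vessel
batch (strict alternation, grading first; the smaller dataset cycles
within the epoch), computes `L = L_dr_ce + L_vessel`, and applies one
optimiser step to all groups; (4) fine-tune — the shared encoder is
frozen (asserted bitwise) while both branches train, after which the
three parameter groups merge into one checkpoint. Stages 1 and 2
deliberately leave all groups trainable — the branch without a gradient
path simply receives no updates — mirroring the protocol's "without
fixing the parameters of any one network".

*Monitoring.* The literal protocol monitors the test set for checkpoint
selection, which leaks test data into model choice. The default here
monitors a held-out fraction of the training data
(`monitor = "holdout"`); `monitor = "provided"` reproduces the literal
behaviour when handed the test set.

*Short sanity runs.* A 200-step run is ~0.5 % of a full-length
training, i.e. the flat head of the cosine schedule, so the scaled-down
learning checks use `schedule = "constant"` (LR pinned at 1e-3) rather
than compressing the entire anneal into 200 steps.

*Determinism.* Initialisation, shuffling, monitoring splits and the
synthetic generator all derive from explicit integer seeds; a repeated
run is bitwise identical. BCE gradients are taken at the logits
(numerically stable), Dice gradients at the sigmoid output; the
engine's backward pass is validated against central finite differences
at `eps = 1e-6` to 1e-4 relative error through the full graph.

## 5. The synthetic generator

The generator is a test instrument, not a clinical simulator. It
emulates exactly the features the pipeline needs: a bright circular
fundus field on a dark surround (radial shading, fundus-like
red-dominant tint); a recursive binary branching vessel tree drawn from
the disc centre with random-walk curvature, caliber multiplied by a
decay factor at each bifurcation, rasterised exactly into the mask
(pre-noise, so masks are perfect); and grade-conditioned lesions —
Poisson-distributed dark microaneurysm-like dots (rate
`lesion_rates[grade+1]`) and bright exudate-like blobs (half that
rate).

Defaults (`synth_config()`): 128² images, trunk caliber 6 px, decay
0.85 per branching, depth 5, vessel contrast 0.45, Gaussian noise
σ = 0.02, lesion rates 0/4/10/18/30, grade histogram following the
canonical 1805:370:999:193:295 class imbalance via largest-remainder
apportionment. Contrast and caliber are deliberately strong so the
1/8-width networks learn both tasks in minutes on one CPU; the mask
foreground fraction stays within the frozen 2–25 % regression band.

What it does **not** emulate: optic disc and macula, vessel
tortuosity/caliber statistics of real retinas, camera vignetting,
inter-image illumination variance, or any actual retinopathy
pathophysiology. A green scaled-down test therefore establishes that
the architecture, losses, gradients and protocol are wired correctly
and can fit a vessel-like signal — it says nothing about clinical
performance on DRIVE/STARE/CHASE_DB1/HRF or APTOS images, which would
require the real datasets and GPU-scale training.

## 6. I/O conventions

Images: `[H, W, 3]` arrays in `[0, 1]`, row-major, origin top-left.
Native on-disk format is PNM (PGM/PPM, ASCII or binary, 8/16-bit) —
chosen because it has a plain-text dialect, keeping all fixtures
human-readable; PNG is supported when the optional `png` package is
installed (GIF is not supported — no decoder exists in a base
scientific R stack). Masks are 0/255 on disk, 0/1 in memory, binarized
on load by the "> half range" rule (127/128 for 8-bit). Images resize
bilinearly, masks by nearest neighbour (stays binary). The train/test
split takes `floor(n · fraction)` training records — the only rounding
consistent with a 2929/733 split of 3662 at 4:1. Model specs and
configs serialise to JSON (YAML opportunistically when the yaml package
is present).

## 7. Known limitations

- CPU-only; the full-width networks are profiled, instantiated and
  cross-checked but not trained at full scale here.
- Deep supervision (`n > 1`) exists in the loss module but is not wired
  into the decoder (which has a single supervised output).
- The batch-norm implementation uses training-mode batch statistics
  with momentum-0.1 running estimates; very small monitoring sets early
  in training can therefore see noisy eval-mode losses.
- The 256-input GFLOPs figure cannot match its published value (see
  Section 2); the package reports the arithmetic truth.
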