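# retinet

Compact multi-task convolutional networks for retinal fundus images, in
pure R (plus two small C++ kernels). The package is aimed at researchers
who want a fully inspectable, CPU-runnable implementation of a modern
vessel-segmentation / retinopathy-grading architecture family — every
layer, gradient, and parameter count is computed by code in this
repository, with no deep-learning framework underneath.

## What it implements

Two networks and the machinery around them:

- **CSP_UNet** — a U-shaped encoder–decoder for per-pixel retinal vessel
  segmentation. The encoder stacks cross-stage-partial (CSP) bottleneck
  blocks with stride-2 convolutions (total downsampling ×16); each of the
  four decoder modules applies atrous spatial pyramid pooling (ASPP,
  dilation rates 6/12/18), a skip concatenation with the matching encoder
  stage, and bilinear ×2 upsampling; a final sigmoid produces a
  probability map binarized at 0.5.
- **MTNet** — hard-parameter-sharing multi-task variant: one CSP_UNet
  encoder shared bitwise between branch I (five-grade diabetic
  retinopathy classification: conv blocks → global average pooling → FC →
  softmax) and branch II (the segmentation decoder). One forward pass
  returns both outputs.

Losses are per-pixel binary cross-entropy plus soft Dice for
segmentation (`L = L_ce + L_dice`, generalising to
`L_vessel = Σ_k λ_k (L_ce^k + L_dice^k)` under deep supervision),
categorical cross-entropy for grading, and their plain sum
`L = L_dr_ce + L_vessel` for joint training. Evaluation pools pixel
confusion counts over the dataset and applies

    Accuracy = (TP+TN)/N        IoU = TP/(TP+FP+FN)
    Precision = TP/(TP+FP)      Recall = TP/(TP+FN)
    F1 = 2·P·R/(P+R)  ( = 2·IoU/(1+IoU) on pooled counts )

Training follows the staged multi-task protocol (Adam, cosine-annealed
learning rate 1e-3 → 2e-7, batch 4, best-monitored-loss checkpointing):
branch I alone, branch II alone, joint training with strict batch
alternation, then a fine-tune with the shared encoder frozen and a final
merge.

A **complexity accountant** counts parameters and multiply–accumulate
operations from first principles over the declarative model spec; the
default widths are calibrated so the accountant reproduces the
architecture family's printed budgets (15.1 M / 46.0 GFLOPs for the
segmentation network at 512², 18.8 M / 24.9 G for grading-only, 24.8 M /
48.5 G for the joint network — a 26.8 % parameter and 31.6 % computation
saving over running the two single-task networks side by side).

A **synthetic fundus generator** (branching vessel trees with exact
masks; grade-dependent dot/blob lesions) makes the whole pipeline
testable on one CPU with no downloads.

## Worked example

```r
library(retinet)

## profile the calibrated segmentation network
spec <- build_csp_unet()
count_params(spec)
#> <ret_complexity> csp_unet
#>   15.1 M parameters (15101337 exact)
count_macs(spec, c(512, 512))
#> <ret_complexity> csp_unet
#>   input 512x512: 46.0 GFLOPs (45995454464 MACs)
#>   15.1 M parameters (15101337 exact)

## tiny-width end-to-end on synthetic data (one CPU, ~3 min)
vessel <- generate_dataset(synth_config(size = 128, n_images = 20,
                                        seed = 11), "vessel")
model <- ret_instantiate(build_branch2_only(hyper = ret_tiny_hyper()),
                         seed = 21)
train_stage2(model, vessel,
             train_config(epochs = 40, seed = 21, schedule = "constant",
                          monitor = "train"))
evaluate_seg_model(model, vessel)
#> accuracy 0.9931  iou 0.9271  precision 0.9572  recall 0.9672  f1 0.9622
```

The first block says the calibrated segmentation spec carries 15.1
million trainable scalars and needs 46.0 giga-MACs for one 512×512
forward pass. The second trains the same topology at 1/8 width on 20
synthetic 128² vessel images for 200 steps and reaches a pooled
training IoU of 0.93 — i.e. the architecture learns the task from
scratch in minutes on a laptop.

The same pipeline is scriptable from a shell via `inst/cli/retinet`
(subcommands `synth`, `split`, `train`, `eval`, `predict`, `profile`).

## Acceptance script

`scripts/acceptance.R` rebuilds the calibrated specs with the installed
package, recomputes every architecture budget (parameters and GFLOPs for
the segmentation, grading-only and joint networks at their stated input
sizes) through the complexity accountant, and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Further reading

The methods vignette (`vignettes/retinet-methods.Rmd`) documents the
model assumptions, the width calibration, the numerical choices
(binarization tie rule, 0/0 metric conventions, probability clipping,
batch-norm handling), what the synthetic generator does and does not
emulate, and known limitations.
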