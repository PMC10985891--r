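---
title: "Two-stage vessel segmentation for fetal 3VV ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage vessel segmentation for fetal 3VV ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The three-vessel view (3VV) is a standard fetal echocardiography plane showing
cross-sections of the pulmonary artery (PA), aorta (Ao) and superior vena cava
(SVC). Segmenting the three vessels supports screening for congenital heart
disease, but it is hard for one-stage segmentation networks: ultrasound images
are dominated by speckle and background clutter, the vessels occupy a small
fraction of the frame, and the SVC is much smaller than the two great
arteries, so it is routinely under-segmented.

`vessel3` implements a two-stage answer to this problem:

1. **ROI localization.** A detector proposes per-class bounding boxes; the
   highest-confidence box per class is kept, the minimum rectangle enclosing
   all kept boxes is expanded by a 5-pixel margin, and the resulting ROI is
   cropped and bilinearly resized to the network input size (256×256 by
   default). An alternative first stage derives the ROI from a coarse binary
   vessel mask instead of boxes; both reduce to the same rectangle geometry.
2. **Fine segmentation.** A Deeplabv3-style fully convolutional network
   segments the crop into the three vessel classes, and the predicted mask is
   mapped back to the original frame through the recorded crop transform.

The two stages are trained independently; there is no end-to-end coupling.
Stage-2 training crops are built from ground-truth boxes (teacher forcing),
with an option to jitter them through the oracle detector so the network sees
imperfect crops.

## Network architecture

The encoder is a cascade of ResNet34-style blocks: a 7×7 stride-2 convolution
(padding 3) with batch normalization, then four groups of two residual basic
blocks each (four 3×3 convolutions per group). The first convolution of
groups 1 and 2 has stride 2; groups 3 and 4 keep stride 1. A 256×256 input
therefore reaches 32×32 at 512 channels (output stride 8).

The multi-scale head replaces atrous spatial pyramid pooling (ASPP) with an
attentional multi-scale feature fusion (AMFF) module: four branches of 3×3
dilated convolutions (padding equal to the rate, so spatial size is
preserved). Two elements distinguish it from plain ASPP:

* **Hierarchical connections.** Branch *i* receives the encoder feature plus
  branch *i−1*'s pre-attention output (element-wise addition, which preserves
  channel count without extra projections), so small-scale evidence flows
  through progressively larger receptive fields.
* **Per-branch spatial attention.** Channel-wise mean and max maps are
  stacked, convolved 7×7, and passed through a sigmoid; the resulting map in
  (0,1) rescales the branch output, so attention can only suppress, never
  amplify.

Branch outputs are concatenated into a 2048-channel fused feature at 32×32.
The decoder reduces it with two convolutions (2048 → 256 → 3), upsamples the
three-channel logits 8× with bilinear interpolation, and applies a
per-channel sigmoid. There is no background channel; a pixel is labeled with
the highest-probability channel above 0.5 (ties to the lower class index),
else background. The ASPP-head baseline — identical branches, no hierarchical
connections, no attention — is constructed by `swap_head()` and is shape-
compatible by construction, which is what makes the head ablation fair.

Choices the architecture description left open, fixed here: branch count 4
with widths equal to the encoder output (forced by 4 × 512 = 2048); dilation
rates (1, 6, 12, 18) following standard ASPP practice at output stride 8;
two residual basic blocks per encoder group (the literal reading of "four
3×3 convolutions"); a 256-channel intermediate decode width; sigmoid rather
than softmax-with-background on the three output channels. Grayscale inputs
are replicated to three channels so pretrained weights could be dropped in,
though random He initialization is the tested default.

## Training loss

The loss is the equally weighted compound
`L = 0.5 · L_dice + 0.5 · L_ce`, with

* `L_ce = −(1/(MN)) Σ_k Σ_i W_k g(k,i) log p(k,i)`, the class-weighted
  cross-entropy over the M = 3 channels and N pixels, where
  `W_k = N_total / N_k` is computed **once over the training split** (a
  per-batch option exists, but the definition of `W_k` is a dataset-level
  frequency). Only positive pixels contribute, exactly as written; false
  positives are penalized by the Dice term.
* `L_dice`, the mean over channels of `1 − (2 Σ g p + ε)/(Σ g + Σ p + ε)`.
  The per-channel summand is already normalized by pixel sums, so the
  natural prefactor is 1/M; a 1/(MN) prefactor would scale the term by 1/N
  and make it vanish for large images, which we treat as a typographical
  slip and do not implement.

Numerical guards: probabilities are clamped to `[1e−7, 1]` inside the
cross-entropy; the Dice smoothing constant is `1e−6`. The analytic gradient
of the compound loss with respect to the probabilities
(`total_loss_grad()`) is verified against central finite differences in the
test suite at 1e−4.

## Optimization schedule

Adam for 35 epochs, learning rate 0.001 stepped down to 0.0001 for the final
10 epochs, with a "decay rate" constant of 1e−8. A single 1e−8 constant does
not identify a unique decay rule: it is far too small to be a per-step
multiplicative learning-rate decay, and it is the canonical value of Adam's
stability epsilon — so the schedule is implemented as a step drop at epoch
25 with 1e−8 exposed as the optimizer epsilon, both configurable. Batch
size defaults to 8.

The compute engine behind training — convolution via im2col/GEMM, batch
normalization, the attention operators and bilinear resampling, each with
reverse-mode gradients on a small tape — is part of this package and is
validated end-to-end by finite-difference checks on every layer type.

## Evaluation metrics

Per class, one-vs-rest: `IoU = TP/(TP+FN+FP)` and `Dice = 2TP/(2TP+FN+FP)`
(reported as percentages; the identity `Dice = 2·IoU/(1+IoU)` is asserted in
tests), plus the symmetric Hausdorff distance between mask boundaries — the
pure maximum of the two directed max–min Euclidean distances, no percentile
variant. Boundaries are foreground pixels with a background 4-neighbor. HD
is reported in pixels at the evaluated resolution. Per-image values are
macro-averaged over the test set, then averaged over the three classes for
the "Mean" row. Classes absent from both masks are undefined and are
excluded from averages (with a count), not scored 100; a class missing from
exactly one mask scores Dice = IoU = 0 but has no defined HD.

## The phantom generator

Clinical 3VV data cannot be redistributed, so every stage is exercised on
synthetic phantoms built to emulate the geometry that matters to the method:

* three near-circular filled ellipses (eccentricity ≤ 1.3) with dark lumens
  (mean 0.08) inside bright walls (0.85) on a mid-gray background (0.45),
  arranged roughly collinearly, left to right PA, Ao, SVC, as in the
  anatomical plane;
* a large size disparity — default lumen radii 14–20 px (PA), 10–14 px (Ao)
  and 3–6 px (SVC) at 256×256, giving the SVC-analog well under a tenth of
  the PA area and making `W_SVC` the dominant class weight, as in the
  clinical class balance;
* multiplicative unit-mean gamma speckle (shape 4 by default; pixel values
  clipped to [0,1]) and a handful of bright elliptical-arc clutter
  structures labeled background, standing in for surrounding tissue
  interference.

Masks label lumens only (0 background, 1 PA, 2 Ao, 3 SVC); boxes are the
exact per-class bounding rectangles. Per-sample seeds are derived from the
master seed, so datasets are bit-reproducible. The generator does **not**
attempt physically accurate acoustics, shadowing, Doppler, or abnormal
anatomy; consequently, passing phantom tests demonstrates that the pipeline,
losses, metrics and optimization behave as specified — not that the trained
weights transfer to clinical images.

The radius ranges are a free choice constrained only by the qualitative
anatomy (the SVC is much smaller); no pixel-size statistics are published
for the clinical images.

## Desk-scale problem sizes

The test suite and the acceptance script run everything on CPU at reduced
scale, chosen once as the smallest sizes that still exercise the full
pipeline: 64×64 phantoms (radii 6–8 / 4.2–5.5 / 2–2.8 px, wall 1.5 px,
inter-vessel gaps 1.5–4 px, clutter 3, speckle shape 6), a width-scaled
network (`base_channels = 8`, dilations 1, 2, 4, 8 matching the smaller 8×8
feature map, 32 decode channels), 120 training / 20 validation phantoms, 30
epochs. Under these conditions the two-stage pipeline with an exact oracle
detector reaches a validation mean Dice comfortably above 0.70; the
memorization check (2 phantoms, 200 epochs, learning rate 6e−3) drives the
training loss below 10% of its initial value. The full-size architecture is
instantiated once per test run to assert the printed shape pipeline
(256×256 → 512×32×32 → 2048×32×32 → 3×256×256). The AMFF-vs-ASPP ablation
runs three seeds at `base_channels = 6` for 10 epochs; at this scale the
per-class deltas are reported with their spread as an experimental outcome,
and their sign is not asserted.

## Degenerate inputs and tie-breaks

* Detector returns nothing → two-stage inference falls back to full-frame
  segmentation (the ROI becomes the whole image).
* Fewer than three classes detected → whatever exists is merged; the missing
  classes are reported.
* Confidence ties in box selection → larger area, then first occurrence.
* Probability ties at labeling → lower class index.
* A class absent from every training mask → class weighting is undefined and
  training aborts with the class named.
* Non-finite loss → training aborts with epoch/batch diagnostics rather than
  continuing silently.

## Known limitations

The phantoms are deliberately simple; no claim is made about performance on
clinical images, which cannot be redistributed. Stage-1 detectors (YOLO-family, Faster-RCNN) are out of
scope: the detector is a pluggable function, and tests use the
ground-truth-jitter oracle. Training is single-threaded CPU R/C++ and is
meant for desk-scale experiments, not full-scale clinical training runs.
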