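---
title: "PSNet: model, training recipe and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PSNet: model, training recipe and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Colorectal polyps are imaged during colonoscopy and segmented on a
pixel level; automated segmentation must cope with diffuse boundaries and a
wide range of polyp sizes, textures and colours. PSNet addresses this with a
*dual* encoder–decoder: a convolutional branch that extracts local detail
and a vision-transformer branch that models global context, fused at
multiple scales.

The assembly is:

* **PS encoder** — four identical (2×2 maxpool → LFE) stages producing a
  feature pyramid at 1/2, 1/4, 1/8 and 1/16 resolution with channels
  64→128→256→512. An **LFE** (local feature extraction) module is two
  depthwise separable convolutions (each followed by batch normalization
  and SiLU) and a **CCM**: two passes of depthwise asymmetric (1×k, k×1)
  plus depthwise dilated (k×k) convolutions with k = 3 (dilation 2) then
  k = 5 (dilation 3), batch normalization after every convolution, a PReLU
  closing the first pass and a ReLU6 the second.
* **Transformer encoder** — a ViT: non-overlapping 16×16 patches, linear
  embedding plus learnable positional embeddings, then L pre-norm blocks of
  multi-headed self-attention and an MLP. The full-size default is ViT-B/16
  (d = 768, L = 12, 12 heads); a tiny variant (d = 64, L = 2, 4 heads) is
  first-class for testing.
* **Partial decoder** — a pointwise linear map from embed dim to μ "tissue
  logit" channels (μ = 64 by default, each channel loosely standing for one
  tissue condition), rearranged row-major into a (H/16 × W/16) grid.
* **Enhanced dilated transformer decoder** — ×4 bilinear upsampling, a
  double standard 3×3 convolution, another ×4 upsampling, a double dilated
  3×3 convolution (rate 3), and two pointwise convolutions down to one
  channel.
* **PS decoder** — four (×2 bilinear upsample → LFE) stages mirroring the
  encoder with U-Net-style channel concatenation of the encoder skips,
  **wSq** attention after stages 2 and 3, **SCSE** after stage 4, and a
  final pointwise convolution to one channel.
* **Four merge modules** — at each pyramid scale the encoder feature map
  and the (bilinearly resized) partial-decoder grid are concatenated,
  projected to a constant 64 channels, passed through two
  (maxpool → double DWSC) and two (×2 upsample → double DWSC) stages, then
  upsampled to full resolution and reduced to one channel.

Each of the six heads emits a full-resolution pre-activation **candidate
segmentation map**. Deep supervision is implemented by averaging:

$$\bar{x} = \tfrac{1}{6}\left(x^{T} + x^{C} + x^{1/16} + x^{1/8} + x^{1/4} + x^{1/2}\right),
\qquad p = \sigma(\bar{x}),$$

and the training loss is the soft IoU complement

$$L = 1 - \frac{\sum p\,y + \varepsilon}{\sum p + \sum y - \sum p\,y + \varepsilon},
\qquad \varepsilon = 10^{-6},$$

computed per image and averaged over the batch. The printed form of the
loss in the source architecture is the IoU ratio itself; a network
*minimizing* that ratio would minimize overlap, so this package implements
the 1 − soft-IoU complement — the direction every IoU-trained segmentation
network uses. Candidate maps are kept pre-activation and the sigmoid is
applied once, after averaging.

## Why the implementation is hand-written

No deep-learning framework is declared as a dependency: every layer
(convolutions, batch/layer normalization, attention, bilinear resampling)
carries an explicit reverse-mode `backward()`, with the memory-bound inner
loops (depthwise convolution, im2col/col2im, per-channel reductions) in
compiled C++ and all channel-mixing products going through R's BLAS. The
test suite verifies each analytic gradient against central finite
differences and each forward pass against independent loop oracles, which
keeps the numerical core honest.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `img_size` | 512 (64 for tests) | input side; divisible by 16 and the patch size |
| `mu` | 64 | tissue-logit channels of the partial decoder; 1/32/64/128 are the studied settings |
| encoder channels | 64,128,256,512 | pyramid schedule; only the final 512 is pinned by the architecture, the doubling schedule is the standard pyramid convention |
| decoder channels | 256,128,64,32 | mirror of the encoder |
| WAP kernel/stride/pad | 7/1/3 | geometry of the weighted average pooling inside wSq; the padded zeros are *included* in the averaging denominator, which is what down-weights border regions ("weighted"); the source study tuned these parametrically without printing them, so they are config-exposed |
| wSq/SCSE reduction | 2 | channel bottleneck of the gates |
| ViT variant | B/16 | the standard ImageNet-21k-pretrained lineage; never printed in the source, config-exposed |
| PReLU slope | 0.25 | common initial value (unstated in the source) |

Training (`train_config()`): Adam (β = 0.9/0.999, no weight decay), batch
16, 400 epochs, learning rate ramping linearly from 2.1052×10⁻⁵ over 20
warm-up epochs and then decaying as `peak·(1−(e−w)/(E−w))^0.98`. The
post-warm-up peak is never printed in the published recipe; the default
here is ten times the initial rate, exposed in the config and flagged as a
gap. Weights: convolutional/linear/positional tensors ~ Normal(0, 0.02),
biases 0, normalization scale/shift exactly 1/0.

## Split protocols

Two protocols are implemented over dataset manifests:

* **standard** — per source, 10% (rounded up) held out for test
  (1000 → 100, 612 → 62); the remaining 1450 records form the training
  pool; validation is a 10% subsample *of that pool* (145). The published
  per-dataset table counts validation inside the training pool
  (900+90+100 and 550+55+62 both overcount their totals); treating
  validation as a subsample drawn from the pool is the only reading
  consistent with the stated pool of 1450, and is what this package does.
  The returned manifest is a strict partition (train 1305 / valid 145 /
  test 162) with `n_train_pool = 1450`.
* **merged** — all five public datasets pooled (2248 records), shuffled,
  224 test and 224 validation drawn, remainder train. The published
  breakdown prints 2023 train records where the arithmetic gives 2024
  (2248 − 224 − 224 = 1800 tagged train plus the 224 validation records in
  the pool); the one-record discrepancy is in the source table and is
  surfaced here rather than silently matched.

## The synthetic generator

`synth_config()`/`synth_generate()` emulate what the network needs from an
endoscopy frame, not how one looks to a clinician: a mucosa-toned
background with low-frequency mottling and pixel noise, a circular
vignette, and 0–3 polyps per frame. Polyp boundaries are circles perturbed
by a low-order radial Fourier series (orders 2–4), scaled anisotropically
and rotated — this produces the smooth blob-like outlines typical of real
polyps without modelling their physiology. Polyps get an additive tone
shift of at least the configured contrast (default 0.25), their own
texture, and a soft specular highlight; the mask is the exact indicator of
the polyp support, so ground truth is noise-free.

Default study conditions used by the tests and the acceptance script:
**8 frames at 64×64 with 1–3 polyps** for the overfit fixture, radius
fractions 0.08–0.22, seeded throughout. What passing tests on this data do
show: the architecture is assembled correctly, gradients reach every
branch, and the optimizer can drive the soft-IoU loss to a near-perfect
segmentation. What they do not show: generalisation to real colonoscopy
appearance (specular clutter, motion blur, instrument artifacts,
inter-patient variability) — benchmark claims on the public datasets
require the real data and the full-scale training recipe.

## Numerical choices

* Resampling is separable bilinear interpolation with the half-pixel
  centre convention; positional-embedding grids transfer across
  resolutions bicubically.
* Maxpool gradients route to the first maximum on ties; ties have measure
  zero for continuous inputs.
* Batch normalization uses batch statistics in training and running
  statistics (momentum 0.1, unbiased) in inference. A 1×1 spatial map with
  batch size 1 makes batch statistics degenerate (the normalized value is
  identically zero); training and gradient-flow checks therefore use
  batch ≥ 2.
* CCM paddings are chosen per layer as `d·(k−1)/2` on the convolved axis,
  the unique size-preserving choice; even effective extents are rejected
  at construction.
* Whether the two CCM passes change the channel count is not pinned by the
  source; they are channel-preserving here, with the channel change carried
  by the first DWSC of the LFE.
* The merge modules consume the partial-decoder grid (not raw tokens):
  the fusion needs 4-D spatial input, and the grid is the transformer
  branch's only spatial form.
* Ablated variants re-average over the streams actually present rather
  than keeping a /6 normalization, so the final sigmoid sees the same
  scale in every variant.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the tiny configuration
(64×64, ViT d = 64/L = 2) everywhere except one full-size 512×512 forward
pass that pins the published shape contract. The overfit check trains the
tiny model on the 8-frame fixture for 200 optimizer steps (batch 2, peak
learning rate 6×10⁻³ after a 5-epoch warm-up — a deliberately aggressive
schedule appropriate for memorising 8 frames, not for real training).

## Known limitations

* Double precision only; no accelerator path. Runtimes target desk-scale
  configurations.
* JPEG decoding is unavailable in this stack; manifests must point at PNG
  or TIFF files.
* Pretrained ViT weights are not shipped; `load_pretrained()` defines the
  loader contract (name-mapped tensor dictionary, positional-embedding
  interpolation, an explicit load report) against this package's own
  `state_dict()` naming.
* The learning-rate peak and the WAP geometry are reasoned defaults for
  quantities the source study withheld; both are config-exposed.
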