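---
title: "Cross-center anisotropic 3D tumor segmentation with hcadan"
author: "hcadan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-center anisotropic 3D tumor segmentation with hcadan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Abdominal CT volumes are strongly anisotropic: in-plane resolution is
typically 0.5--1.0 mm while slice spacing is 5--8 mm. Tumors are small
relative to the background, their shape and intensity vary widely, and
multi-center cohorts add a second difficulty: scanners and protocols differ
between hospitals, so a segmentation model trained on data from some centers
degrades on a new center (domain shift). `hcadan` implements a complete
pipeline for this setting:

* **AsTr**, a segmentation backbone that treats the in-plane and
  through-plane directions separately, models long-range context with a
  deformable transformer, and refines boundaries with pyramid
  boundary-aware (PBA) blocks; and
* **HCADA**, hierarchical class-aware domain alignment: unsupervised
  adversarial adaptation that aligns multi-scale features between a labeled
  source domain and an unlabeled target domain, with the adversarial signal
  gated by a voxel-wise class attention map.

Because no clinical multi-center dataset ships with the package, a synthetic
phantom generator provides anisotropic volumes with ellipsoidal tumors and
controllable inter-domain shifts; every component is exercised end-to-end on
phantoms.

## The AsTr backbone

**Anisotropic encoder.** A Conv-GN-PReLU stem is followed by two in-plane
(1x2x2) average poolings, each preceding a stage of *AsBlocks*
(2 and 3 blocks). An AsBlock runs two parallel convolutions — 1x3x3
(in-plane) and 3x1x1 (through-plane) — concatenates them with a
1x1x1-projected copy of the input and projects back to the stage width, so
x-y and z context are extracted independently, matching the voxel
anisotropy. Two stages of squeeze-and-excitation residual (SE-Res) blocks
(3 and 2 blocks) follow, each first block downsampling isotropically (2x2x2)
by strided convolution. The result is a 4-level feature pyramid; level 1 is
the coarsest.

The full-scale default widths are (16, 32, 64, 128) per stage with a
`width_mult` scale (widths are not prescribed by the architecture itself).
Where the two early average poolings sit relative to the AsBlock stages is a
genuinely open layout question; `hcadan` pools immediately before each
AsBlock stage, which gives the documented pyramid
16x64x64 → 16x32x32 → 16x16x16 → 8x8x8 → 4x4x4.

**DeTrans context encoder.** The pyramid is projected to a shared embedding,
flattened into one token sequence with 3D sinusoidal positional encoding and
a learnable per-level embedding, and passed through N deformable-transformer
layers. Each multi-scale deformable self-attention (MS-DMSA) step lets every
query attend to a handful of learned sampling points on every pyramid level
(attention weights softmaxed jointly over points and levels, trilinear
sampling in between grid nodes), followed by a feed-forward network, both
with residual connections and layer normalization. Defaults follow the
deformable-transformer lineage: 4 layers, 6 heads, 4 points. The embedding
width must split across heads, so the default is 126 (6 heads x 21) rather
than a power of two. Offset projections initialize to zero weights with
small random biases; attention-weight projections initialize to zero, i.e.
uniform attention.

**Boundary-aware decoder.** Decoding mirrors the encoder (SE-Res stages at
the coarse levels, AsBlocks at the fine levels, one block per stage) with
non-overlapping transpose convolutions for upsampling; the reshaped
transformer output and the encoder skip of each level are added
element-wise. A PBA block sits at every level: for pooling kernels k in the
level's kernel set, the feature grid F is average-pooled with a stride-1
"same" window, and `sigmoid(F - avgpool_k(F)) * F` forms a soft boundary
response; the responses are channel-concatenated and a 1x1x1 convolution
restores the channel count. Kernel sets are 3/5 at the two coarse levels and
5/7 at the two fine levels. The pooled mean uses a valid-count divisor so a
constant field pools to itself exactly, including at borders — this makes
the constant-input contract (every branch equals 0.5 F) exact. A final
Conv-GN-PReLU and 1x1x1 head emit 2-channel logits at full patch
resolution. The four post-PBA feature grids are returned for alignment;
with `use_pba = FALSE` (ablation) the pre-PBA features take their place.

## Hierarchical class-aware domain alignment

For each pyramid level an independent U-Net discriminator receives the
(channel-projected, trilinearly upsampled to patch resolution) alignment
feature and emits an unbounded per-voxel domain score. The least-squares
adversarial targets are +1 (source) and -1 (target):

* discriminator objective, per level:
  `L_dis = mean((D(f_s) - 1)^2) + mean((D(f_t) + 1)^2)`;
* adaptation objective on the segmentor, per level:
  `L_da = mean(att * (D(f_t) - 1)^2)`,

where `att` is the tumor channel of the class attention map — the voxel-wise
softmax of the segmentor's own logits — so alignment pressure concentrates
where the model sees tumor evidence. Both are combined across levels as
`sum_l lambda_l * L^l` with `lambda = (1/8, 1/4, 1/2, 1)` from coarse to
fine: the weight halves with each resolution halving ("decreases
exponentially" is the design constraint; the base 1/2 is configurable).
Voxel *means* (rather than sums) are used inside each level so that the
lambdas weight levels, not voxel counts.

Three deliberate choices where the method description is silent:

* the attention map is treated as a constant (gradient-blocked) inside
  `L_da`, otherwise the segmentor could reduce the loss by collapsing its
  tumor probability rather than aligning features;
* the discriminators are 3-level U-Nets (16/32/64 channels scaled by
  `width_mult`, leaky-ReLU, *linear* output head — least-squares targets of
  +/-1 need an unbounded range); a 1x1x1 channel projection is applied at
  feature resolution before upsampling so the full-resolution U-Net stays
  affordable;
* only the tumor attention channel gates the alignment — with two classes
  the background channel is redundant (the channels sum to 1).

Ablation modes mirror the method's ablation arms: `m1` aligns only the
finest level, `m2` replaces the attention map by 1 (class-agnostic), `off`
reduces exactly to supervised training.

## Losses and metrics

Segmentation is trained with `L_seg = L_dice + L_bce`. The Dice term is the
soft form `1 - 2 sum(p g) / (sum(p^2) + sum(g^2))`; with both masks empty it
is defined as 0. The cross-entropy term is the standard negative-log form,
voxel-averaged, with probabilities clamped at `1e-7` (the loss is meant to
be minimized, so the conventional sign is used). For two classes the softmax
tumor probability is computed as a sigmoid of the logit difference.

Evaluation uses DSC and Jaccard (percent; two empty masks score 100 by
convention) and physical surface distances: surfaces are foreground voxels
with a face-adjacent background voxel (the outside of the grid counts as
background; 26-connectivity would be the other defensible choice), distances
are Euclidean in mm after scaling by the voxel spacing. ASD is the average
of the two directed mean surface distances; HD95 the maximum of the two
directed 95th-percentile distances, percentiles by linear interpolation
between order statistics. Empty masks make the distance metrics undefined;
such cases are flagged (`distance_defined = FALSE`) and excluded from the
mean +/- SD summaries. The test suite checks all four metrics against
exhaustive brute-force set/distance oracles on random masks.

## Preprocessing

Intensities are clipped to the 0.5/99.5 foreground percentiles (linear
interpolation between order statistics) and z-scored by the clamped
foreground mean/SD, the CT scheme popularized by nnU-Net;
a zero-variance foreground yields an all-zero volume. `clip_normalize()`
does this per volume, but the *trainers* compute one set of cohort
statistics from the pooled source-training foreground and apply it to every
volume, source and target alike: per-volume z-scoring would silently remove
exactly the inter-center intensity shift that adaptation is supposed to
handle, and target volumes have no masks to normalize by.

Resampling to the target grid (5.0 x 0.741 x 0.741 mm by default, 8.0 mm
slice spacing supported the same way) is separable per-axis interpolation on
a node-centered grid: cubic splines for images (order 3; linear ramps are
reproduced to machine precision, the property the test suite checks), linear
(order 1) as an option, nearest neighbor (order 0) for masks so labels stay
binary. The output shape per axis is `round(shape * spacing / target)`.

Training patches are tumor-centered with a seeded uniform jitter of up to
25% of the patch extent, clamped into the volume where it fits and
zero-padded where it does not. The trainer draws such a patch with
probability `fg_patch_prob = 0.5` and a uniform-random patch otherwise:
training exclusively on tumor-centered patches produces severe false
positives at sliding-window inference, because background-only windows are
never seen (we measured DSC collapsing from ~80 on centered patches to ~23
on full volumes in that regime). Augmentation applies seeded per-axis flips
(p = 0.5), in-plane 90-degree rotations (p = 0.25) and integer in-plane
translations (<= 5 voxels) identically to image and mask.

## Training

SGD with momentum 0.99 and initial learning rate 1e-3, batch size 2, and a
polynomial decay `lr (1 - t/T)^0.9`; the full-scale recipe is 500 epochs of
250 iterations. Adversarial training alternates per iteration: a segmentor
step minimizing `L_seg + w_da * L_da^h` through the current discriminators,
then a discriminator step minimizing `L_dis^h` on the same (detached)
features — reusing the features halves the forward passes; the
discriminator therefore sees features from the segmentor as it was at the
start of the iteration. Unstated hyperparameters were fixed once:
`w_da = 0.01` (keeps `L_seg` dominant, the usual LSGAN-UDA magnitude),
discriminator SGD at lr 1e-4 (a slower discriminator stabilizes
least-squares adversarial training). A non-finite loss aborts with a
diagnostic rather than training on. Target-domain cases must be supplied
mask-free (`unlabeled_set()`); the trainer rejects masked target cases, so
target labels are provably unread during adaptation.

Inference is sliding-window with 50% overlap and logit averaging, argmax to
a binary mask. The network is fully convolutional, so a window covering the
whole volume (single-pass inference) is equally valid and is what the
package's own experiments use for speed.

## The phantom generator

Each phantom is an ellipsoidal "tumor" (seeded random center, in-plane
orientation, and semi-axes spanning a > 4-fold volume range) on a background
of three seeded low-frequency cosine fields plus Gaussian noise, on an
anisotropic grid (5 mm slices, ~0.74 mm in-plane by default). The tumor edge
carries a ~1-voxel partial-volume ramp by default (`soft_boundary`), making
boundary refinement measurable; with the ramp off, a noiseless, texture-free
phantom takes exactly two intensity values. Inter-domain shifts compose an
additive intensity offset, a contrast scale about the background mean, a
noise-SD ratio, and a slice-spacing change (the target grid keeps the
physical z extent, so 16 slices at 5 mm become 10 at 8 mm).

What the phantoms do *not* emulate: organs and anatomy, beam hardening,
Hounsfield calibration, partial-volume effects beyond the single-voxel ramp,
or inter-observer label noise. Passing tests on phantoms therefore
demonstrates that the machinery — preprocessing, architecture, objectives,
adaptation dynamics, metrics, protocols — is correct and that adaptation
recovers a synthetic intensity/spacing shift; they say nothing quantitative
about clinical CT performance.

## Numerical core and problem sizes

No neural-network framework is assumed: the package carries a compact
tape-based reverse-mode autodiff engine over dense arrays with compiled
kernels (direct 3D convolutions, separable box-filter pooling with
valid-count divisors, non-overlapping transpose convolutions, trilinear
resizing, deformable-attention sampling with gradients w.r.t. values,
locations and weights, all verified against central finite differences in
the test suite). Convolution weights use He initialization; GN groups
default to 8, reduced to the largest divisor of the channel count;
group/layer normalization use eps = 1e-5. Ties in the argmax go to
background (`tumor > background` strictly).

The package's own experiments run a **desk profile** sized from timing and
FLOP arithmetic so a full adaptation study fits on one CPU core: 16x64x64
phantoms, `width_mult = 0.25`, a 2-layer / 2-head / 2-point / 32-dim
DeTrans, batch 1 per domain, and single-window full-volume inference.
Training patches are 16x32x32 by default; the cross-domain study uses
8x32x32 patches for 100 iterations per arm — the smaller through-plane
extent halves the per-iteration cost, which is what buys a schedule long
enough for the baseline to converge and for the ramped adversarial weight
to reach full strength (the supervised overfit check runs 200 iterations at
the default patch). The full-scale profile (28x256x256 patches, widths
(16, 32, 64, 128), DeTrans 4/6/4/126, batch 2, 500 x 250 iterations) is the
package default and is recommended only with substantial compute. The desk
profile also rescales the optimizer: lr 0.01 with momentum 0.9 keeps the
effective step of the full-scale recipe (lr/(1 - momentum) = 0.1) but is
stable within short schedules, where momentum 0.99 diverges or stalls; this
was calibrated on the supervised baseline alone, and the discriminator rate
(1e-3 at desk) preserves the same segmentor:discriminator ratio.

## Known limitations

* The desk-scale adaptation study is directional: it checks the *ordering*
  of the adaptation arms on a synthetic shift, not clinical effect sizes.
* Exact parameter/FLOP parity with any published configuration is out of
  scope; channel widths, GN groups and transformer sizes required for such
  parity are not architecture constants, and `network_summary()` exists to
  probe configurations.
* The spline resampler is separable per axis (tensor-product interpolation),
  not a global 3D spline fit; for CT-like data these agree to interpolation
  accuracy.
* Discriminator updates reuse features from the segmentor state at the
  start of each iteration (see Training); with `w_da` and the slow
  discriminator learning rate this is indistinguishable in practice from
  strict alternation but is not literally identical.
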