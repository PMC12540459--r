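---
title: "Edge-guided multimodal segmentation of focal cortical dysplasia: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-guided multimodal segmentation of focal cortical dysplasia: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lemunet)
```

## The problem

Focal cortical dysplasia (FCD) is a malformation of cortical development and a
leading cause of drug-resistant epilepsy. FCD lesions are small, morphologically
diverse and — critically — have poorly defined edges on MRI; a substantial
fraction of patients are "MRI-negative", with lesions visible only as subtle
multimodal signatures (e.g. hypometabolism on FDG-PET). Automatic segmentation
therefore benefits from (i) multimodal input (T1, FLAIR, PET), and (ii)
mechanisms that explicitly direct the network's capacity toward lesion *edges*.

`lemunet` implements an edge-guided 3D encoder-decoder segmentation network for
this task, together with the evaluation methodology used in the FCD literature
(detection rates at Dice thresholds, cluster-level false-positive counting,
HD95), and a synthetic multimodal phantom generator so that the full pipeline is
exercisable and testable without patient data.

## Model

### Backbone

The backbone is a MedNeXt-style ConvNeXt encoder-decoder. Each block applies a
depthwise $k^3$ convolution, per-channel group normalization, a $1^3$
expansion convolution to $R \cdot C$ channels with GELU, a $1^3$ compression
convolution, and a residual addition. Four 2$\times$ down blocks (strided
depthwise convolution with a $1^3$ stride-2 residual projection) and four
2$\times$ up blocks (the transposed counterparts) connect five resolutions;
skips are additive. A softmax head sits at each of the five decoder
resolutions (deep supervision, full resolution first).

Two named configurations follow the reference compound-scaled recipes:

* **M**: $C = 32$, $B = (3,4,4,4,4,4,4,4,3)$, $R = (2,3,4,4,4,4,4,3,2)$
* **L**: $C = 32$, $B = (3,4,8,8,8,8,8,4,3)$, $R = (3,4,8,8,8,8,8,4,3)$

where $B$ and $R$ are per-stage block counts and expansion ratios (4 encoder
stages, bottleneck, 4 decoder stages). With 3 input channels and 2 classes the
package counts 17,550,954 trainable parameters for M with kernel 3 and
61,781,258 for L — the complexity anchors verified by the test suite. Every
convolution carries a bias and every normalization an affine pair; these
conventions match the reference architecture and are what the L-configuration
count confirms exactly.

### Laplacian edge attention (LEA)

High-frequency edge information is supplied by a 3D Laplacian pyramid of the
(preprocessed) T1 channel: $N_0 = N$, $N_{k+1} = d(gs(N_k))$,
$L_k = N_k - up(N_{k+1})$, where $gs$ is separable binomial smoothing, $d$ is
2$\times$ decimation and $up$ trilinear upsampling. Levels $L_0$ and $L_1$
(full and half resolution) feed the two LEA blocks.

Each LEA block receives the main-encoder feature $f_e^i$, the feature
$f_{e\text{-}T1}^i$ of a *dedicated* single-channel T1 encoding branch (own
stem and blocks mirroring the first two encoder stages; weights not shared),
and the pyramid level $f_l^i$. Both encoder features pass through separate
CBAM modules (channel attention: shared MLP over global average and max pooled
channel vectors; spatial attention: a $7^3$ convolution over the channel-wise
mean and max maps; both gates sigmoid). They are mixed by a learnable scalar
$\lambda$ (initialized at 0.5) with the complementary weight $\beta = 1 -
\lambda$ enforced structurally, followed by batch normalization:

$$ f_{map}^i = \mathrm{BN}\big(\mathrm{CBAM}(f_e^i)\,\lambda +
   \mathrm{CBAM}(f_{e\text{-}T1}^i)\,(1-\lambda)\big). $$

The pyramid level is then fused by a sigmoid gate applied to the raw
concatenation, a $1^3$ convolution back to $C$ channels, batch normalization
and GELU:

$$ map^i = \sigma(\mathrm{con}[f_l^i, f_{map}^i]), \qquad
   f_{edge}^i = g(\mathrm{BN}(\mathrm{Cov}(map^i))). $$

Applying the sigmoid to the concatenation *before* the convolution is unusual;
the package implements the formula literally as published.

### Multi-strategy feature fusion (MFF)

At decode time, the high-frequency residual of a decoder feature,
$M^i = f_d^i - up(d(gs(f_d^i)))$ (computed per channel with the same pyramid
operators), gates the edge features:

$$ f_{mff}^1 = \sigma(M^1) \odot f_{edge}^1, \qquad
   f_{mff}^2 = \sigma(M^2) \odot \big(f_{edge}^2 +
      \mathrm{Cov}(d(f_{edge}^1)) \odot I\big),\quad
   I = \sigma(\mathrm{Cov}(f_{edge}^2)). $$

$f_{mff}^2$ is added to the decoder feature at the penultimate resolution and
$f_{mff}^1$ at full resolution; fusion is plain addition with no extra
normalization, so forcing both fused features to zero reduces the network
*exactly* to the plain backbone (an invariant asserted bitwise in the tests).

Design choices made where the published description is open:

* $f_d^i$ is taken as the decoder feature *after* the additive skip (the
  feature that enters the stage's blocks).
* $d(f_{edge}^1)$ in the second fusion is plain stride-2 subsampling without
  Gaussian pre-smoothing — the formula names $d$ alone, unlike the $gs \circ d$
  composition inside $M^i$.
* $I$'s convolution preserves the $2C$ width of $f_{edge}^2$.
* The two CBAMs of a LEA block have separate weights (they attend different
  feature statistics); $\lambda$ is an unconstrained trainable scalar, one per
  LEA block.
* The T1 branch is trained jointly with the rest of the network.

### Loss

Training minimizes the deep-supervision composite loss

$$ L = \sum_{i=1}^{D} w_{dice}^i\, L_{Dice}(f_{DS}^i, f^i)
      + w_{ce}^i\, L_{CE}(f_{DS}^i, f^i) $$

with $D = 5$ levels, soft Dice in the squared-denominator form with smoothing
$10^{-5}$ over foreground classes, mean-voxel cross-entropy, and the halving
weight scheme $w^i \propto 2^{-(i-1)}$ normalized to sum 1 with
$w_{dice}^i = w_{ce}^i$ (the convention of the framework family the backbone
derives from; the publication leaves the weights unstated). Ground truth is
decimated to each level by nearest-neighbour subsampling.

## Numerical and engineering choices

* **Autodiff.** The network's forward and reverse passes are hand-written; the
  heavy 3D convolutions (depthwise, transposed depthwise, and the dense CBAM
  spatial kernel) are small C++ kernels, pointwise convolutions are BLAS
  matrix products. Every primitive's gradient, and the assembled network's
  gradient, are verified against central finite differences in the test suite
  (directional derivatives agree to ~1e-6 relative).
* **Normalization statistics.** Batch size is 2 in the published training
  configuration, so batch statistics are unreliable; blocks use group
  normalization with one group per channel, and the LEA "BN" layers compute
  per-sample (instance) statistics at train and test time. This keeps
  inference deterministic and batch-size independent.
* **Initialization.** Kaiming-uniform fan-in initialization
  ($U(\pm 1/\sqrt{fan_{in}})$, zero biases), the default of the reference
  framework. Heavier-tailed schemes make the 9-stage residual chain amplify
  activations until the softmax saturates at initialization.
* **Pyramid conventions.** The Gaussian kernel and border rule are not stated
  in the publication; the package uses the classic 5-tap binomial
  $[1,4,6,4,1]/16$ with reflect borders (unit sum, symmetric), which preserves
  constants and interior affine ramps, and ceil-halving shapes with an
  explicit upsampling target so reconstruction is exact. The pyramid is built
  from the *preprocessed* (z-scored) T1 channel so its magnitudes are
  comparable across cases.
* **Optimizer.** AdamW ($\beta = (0.9, 0.999)$, $\epsilon = 10^{-8}$,
  decoupled weight decay $10^{-5}$), constant learning rate $10^{-3}$,
  matching the published settings where stated.
* **Empty-mask conventions.** $DC(\emptyset,\emptyset) = 1$; precision/recall
  with $0/0$ denominators are 0; HD95 of an empty mask is undefined and
  excluded from cohort averages. These are recorded per case so cohort numbers
  are reproducible.
* **HD95** is computed over all foreground voxel centers (the defining
  point-set formula), with linearly interpolated percentiles.
* **Slice detection rates** count only ground-truth-bearing slices in the
  denominator and average the three axes unweighted; the publication does not
  pin down the denominator, and this choice is stated in the report objects.
* **Post-processing** (largest 26-connected component, kept only when the
  case's DC strictly improves) is applied per case; by construction it never
  lowers DC.

## Preprocessing

The published pipeline delegates preprocessing to its segmentation framework;
the package implements that framework's default chain explicitly: crop to the
joint nonzero bounding box, resample to 1 mm isotropic spacing (trilinear for
images, nearest-neighbour for masks), z-score each modality over its nonzero
voxels, and center pad/crop to a fixed grid (128³ in the production
configuration). An inverse record maps predictions back to the native grid.
Modalities absent from a case are dropped, with T1 always first (it feeds the
pyramid and the T1 branch).

## The synthetic phantom

The generator emulates the *structure* of the task: an ellipsoidal head
containing a smooth two-compartment tissue field (a thresholded correlated
Gaussian random field) whose compartment intensities are modality-specific —
a wide gray/white split on T1 (0.45/0.80), a narrow one on FLAIR (0.55/0.65,
matching FLAIR's weak tissue contrast) and intermediate on PET (0.50/0.70) —
plus small ellipsoidal lesions with Gaussian-blurred edges, per-modality
lesion contrast (T1 slightly hypointense at -0.15, FLAIR-analog hyperintense
at +0.35, PET-analog hypometabolic at -0.30), and additive Gaussian noise
(sd 0.05). The FLAIR lesion contrast deliberately exceeds the FLAIR tissue
split, so simple thresholding recovers the lesion — the validity oracle the
generator's tests rely on. The ground truth is the
pre-blur lesion support, lesion volume is kept under 2% of the head, and output
is fully seed-deterministic.

What it does *not* emulate: cortical folding and the gray-white boundary
geometry where real FCDs sit, scanner bias fields, inter-modality registration
error, and the extreme subtlety of MRI-negative lesions. Passing tests on the
phantom therefore demonstrate that the architecture, losses, gradients,
metrics and pipeline are implemented correctly and can learn lesions of this
kind — not that the network reaches clinical performance; the published
patient-data scores require the original cohorts and GPU-scale training.

## Problem sizes used in the checks

Desk-scale runs keep the suite fast while exercising every code path: the
network checks use a reduced configuration ($C = 8$ or 4, one block per stage)
on 16³–32³ grids; the learning check overfits a single 32³ synthetic case to
training Dice > 0.9 within 300 AdamW steps (with early stopping once the
threshold is reached); metric oracles run on hundreds of random 12³ mask
pairs; the parameter-count anchors build the full M and L models once.

## Known limitations

* Whole-volume inference only at grids divisible by 16; no sliding-window
  mode or test-time augmentation.
* Single-sample processing (gradient accumulation implements batches), so
  wall-clock training is CPU-bound and intended for reduced configurations.
* The published complexity table could not be reproduced exactly for every
  row under any single parameter-counting convention; the L configuration
  matches exactly and the discrepancy analysis lives with the parameter-count
  checks.
* The learnable $\lambda$ is reported per block but not constrained to
  $[0,1]$; its published role is an initialization, and the mixing formula
  imposes no constraint.
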