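---
title: "Usformer: model, training objective, and evaluation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Usformer: model, training objective, and evaluation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usformer)
```

## The problem

Left-atrial (LA) fibrosis assessment from 3D late gadolinium-enhancement
(LGE) cardiac MRI requires a segmentation of the LA cavity, conventionally
traced slice by slice by hand. Automatic segmentation of these scans is
hard for reasons that are structural rather than incidental: the LA is a
tiny fraction of the volume (strong class imbalance), its boundary contrast
against neighbouring blood pools is poor, image SNR is low, and the target
includes long thin appendages (pulmonary vein sleeves, the atrial
appendage, the mitral valve plane) that thicker networks smear out. Most 3D
approaches cope with volume size by running two stages -- locate a region of
interest on a downsampled scan, then segment a crop -- at the price of error
propagation between the stages.

This package implements a single-stage alternative: a lightweight U-shaped
3D encoder-decoder whose two deepest stages are *transformer* stages built
on transposed (channel-wise) attention, trained end to end on full volumes
and producing a per-voxel probability map that is simply thresholded. No
ROI cropping, no post-processing.

## The network

The encoder has three convolutional stages followed by two transformer
stages; the decoder mirrors the resolution ladder with skip connections at
every level.

* **Convolutional stages** (levels 1-3): two blocks of
  [3x3x3 convolution, instance normalization, rectifier] at channel widths
  C1, C2, C3, each stage followed by 2x2x2 max pooling.
* **Transformer stages** (level 4 and the bottleneck): a 3x3x3 channel-lift
  convolution to C4 (resp. C5), a transformer block, a 3x3x3 convolution,
  then max pooling (level 4) or transposed-convolution upsampling (the
  bottleneck).
* **Decoder** (levels 4-1): 2x2x2 transposed-convolution upsampling,
  concatenation with the same-resolution encoder feature map, and one
  [conv, norm, rectifier] block back to the level's width.
* **Head**: a 1x1x1 convolution to one channel and a logistic squashing;
  output values are probabilities in [0, 1].

Default channel widths are 16/32/64/128/256. Four poolings mean input grids
must be divisible by 16; `pad_to_multiple()` pads arbitrary grids (with the
volume minimum, which after z-score normalization approximates MRI
background better than zero) and records how to crop back exactly.

With these defaults the network has 5,717,665 trainable parameters
(~5.72M). Counting choices that the architecture outline leaves open were
fixed once, before any training, with a small parameter budget in mind: two
convolutions per encoder stage but only one per decoder stage (a heavier
two-convolution decoder would add ~0.6M parameters while the decoder's job
here is mostly upsampling fused with skip evidence), feed-forward expansion
2, bias-free attention projections including an output projection, and
learnable transposed-convolution upsampling (trilinear interpolation is the
usual alternative; the learnable version keeps the whole decoder trainable
end to end).

### Transposed attention

A conventional attention module on a feature grid with $n = \hat H \hat W
\hat Z$ voxels and $\hat C$ channels forms an $n \times n$ score matrix --
hopeless for full 3D volumes where $n$ runs into millions. Transposed
attention swaps the roles of space and channels. From a layer-normalized
input, bias-free 1x1x1 convolutions produce $Q, K, V \in \mathbb{R}^{n
\times \hat C}$, and the module computes

$$A(V, K, Q) = V \, \sigma(K^{\top} Q),$$

where $K^\top Q$ is $\hat C \times \hat C$ and $\sigma$ is a column-wise
softmax, so each column is a probability distribution over channels and
each output channel is a convex combination of $V$'s channels. The cost is
$O(\hat C^2 n)$ -- linear in the voxel count, quadratic only in the channel
count -- and no $n \times n$ object is ever materialized. The module's
memory high-water mark is $O(n\hat C + \hat C^2)$.

Choices the formula leaves open, fixed as follows:

* **Softmax axis**: column-wise over the $\hat C \times \hat C$ score
  matrix. This is the orientation under which the product $V\sigma(\cdot)$
  mixes channels convexly; the package asserts each column sums to 1.
* **No temperature**: the score product enters the softmax unscaled.
* **Single head**: multi-head variants exist but add bookkeeping without
  evidence of benefit at these widths.
* **Residual pathways**: the transformer block is pre-norm residual,
  $y = x + \mathrm{Attn}(\mathrm{LN}(x))$, $z = y +
  \mathrm{FFN}(\mathrm{LN}(y))$, with the FFN a pointwise expansion to
  $2\hat C$, rectifier, and projection back. Residuals are included because
  stacked normalized blocks without them are effectively untrainable; the
  block reduces exactly to the identity when its branch output projections
  are zero, which the test suite exploits.

`transposed_attention()` exposes the operator functionally;
`attention_flops()` and `estimate_flops()` give the analytic cost model
(every term in the network's cost table is linear in $n$, so doubling every
spatial dimension multiplies total FLOPs by exactly 8). The printed
per-layer `summary()` cross-checks the analytic table against the built
network's exact parameter count.

## The objective

Training minimizes

$$L_{seg} = L_{dice} + \lambda\, L_{BCE},$$

where $L_{dice} = 1 - (2\sum Y\hat Y + \varepsilon)/(\sum Y + \sum \hat Y +
\varepsilon)$ is the soft dice loss and $L_{BCE}$ the mean binary
cross-entropy, with $\lambda = 1$ by default (selected in the original
study from a sweep over 0, 0.1, 0.5, 0.9, 1, 10, 100). The dice term is
area-based: appending background to both arguments leaves it unchanged,
which is what makes it robust to the severe class imbalance; BCE, a
per-voxel mean, is *not* invariant to background -- but it stabilizes
optimization when the foreground is small and dice gradients become
erratic. Numerical choices: the dice denominator is the soft sum
$\sum Y + \sum\hat Y$ (the set-union reading would make a perfect
prediction score $-1$, contradicting the Dice = $2TP/(2TP+FN+FP)$
evaluation metric); smoothing $\varepsilon = 10^{-5}$ keeps empty masks
defined; BCE uses mean reduction so $\lambda$ means the same thing at
every volume size; probabilities are clamped to $[10^{-7}, 1-10^{-7}]$
inside the logarithms. The gradient with respect to the head logits is
composed analytically (for BCE it collapses to $(\hat Y - Y)/n$), avoiding
the usual instability of differentiating through the clamped logarithm.

## Training and inference

The optimizer is SGD with momentum 0.9 (momentum, batch size 2 and zero
weight decay are package choices; the published recipe does not state
them), cosine annealing from an initial learning rate over the configured
epochs: $\eta_e = \eta_0 \cdot \tfrac12(1 + \cos(\pi e/E))$, the standard
half-cosine to zero. Augmentation is applied on the fly with probability
0.5 per scan: one in-plane (IJ, axial) affine -- scale in (0.5, 1.5),
rotation in (-25°, 25°), translation in (-10, 10) pixels -- drawn once per
scan and applied identically to every slice (independent per-slice draws
would shear the anatomy across slices); the 50% gate covers the three
components jointly. Images are resampled bilinearly, masks by nearest
neighbour so they stay exactly binary; out-of-field voxels are filled with
the volume minimum (image) and 0 (mask).

One optimization detail matters under the severe class imbalance: with a
zero-initialized head, the early gradient field is dominated by the
background and the logistic output can saturate toward the empty
prediction, after which both loss terms go silent (the dice gradient
carries a factor $\hat Y(1-\hat Y)$). `fit()` therefore initializes the
head bias to the log-odds of the training foreground fraction before the
first epoch (`init_head_prior`, on by default), starting the network at
the base rate where both terms pull the foreground up cooperatively. This
is the standard prior-initialization remedy for rare-foreground detection
heads.

Inference is single-stage: z-score normalize, pad to a 16-divisible grid,
one forward pass, crop back, threshold at 0.5 (voxels strictly exceeding
the threshold are foreground). The original study reports dice varying by
only 0.01% across thresholds 0.1-0.9, so nothing delicate hinges on the
value. When a validation set is supplied, `fit()` retains the
best-validation-dice weights (the model-selection rule is a package
choice).

Everything is seeded: weight initialization, shuffling, augmentation draws
and phantom generation all flow from the configured seeds through R's RNG,
and `fit()` is bit-reproducible under a fixed thread policy.

## The phantom generator

Clinical LGE data cannot ship with a package, so the generator produces
volumes that reproduce the *properties that make the task hard* rather
than the anatomy: a random ellipsoid body with 2-4 curved tubular
appendages (pulmonary-vein-like) and an optional extra lobe, a foreground
fraction confined to 0.5-5% of the volume (class imbalance), a
foreground-background intensity gap of 1.5 noise standard deviations with
the clean signal blurred by a 1-voxel Gaussian before noise is added
(indistinct boundaries), and additive Gaussian noise. Default grid 64 x 64
x 32 at 1.25 x 1.25 x 2.5 mm spacing -- the acquisition resolution of the
public challenge data, at a desk-scale matrix size. Shape parameters are
redrawn until the mask is one 6-connected component inside the fraction
bounds; regeneration rather than morphological repair keeps the geometry
honest. Gaussian (not Rician) noise is a simplification; the generator
also does not model fibrosis texture, vendor intensity variation, or
oblique orientations. Tests passing on phantoms therefore demonstrate that
the pipeline's mechanics are correct and that the model can learn
low-contrast, imbalanced, tubular targets -- not that any particular
clinical dice level would be reached.

## Evaluation metrics

Per scan: 3D Dice $= 2TP/(2TP+FN+FP)$ over the whole volume; full
(not 95th-percentile) symmetric Hausdorff distance; and average symmetric
surface distance, both in physical millimetres between voxel centres,
honouring anisotropic spacing. A surface voxel is a foreground voxel with
at least one background 6-neighbour, with the array border counted as
background. The ASSD denominator is $|P| + |G|$, the surface cardinalities
(the only reading under which the statistic is an average of surface
distances). Both-empty-mask Dice is defined as 1 with a warning; surface
distances with an empty surface are an error. Aggregates report mean and
population SD across scans. All three metrics are verified against
brute-force all-pairs oracles in the test suite.

## Problem sizes used in the shipped checks

The package's own end-to-end demonstration trains a reduced network
(channels 4/8/16/32/64, ~0.36M parameters) on twenty 64 x 64 x 32 phantoms
with the full pipeline and evaluates on five held-out phantoms; the
training-set-size sweep (`learning_curve()`) uses 32 x 32 x 16 phantoms
and sizes 4 vs 16 with three replicates, reproducing the qualitative
"more labeled scans help, with diminishing returns" shape. For the desk
runs the initial learning rate is raised from the clinical-recipe 0.001
(tuned for 200-epoch schedules on large scans) to suit the short
schedules; the learning-rate *schedule shape*, loss, optimizer and
augmentation are exactly the pipeline described above. These sizes were
chosen so the whole suite runs comfortably on a single CPU core.

## Known limitations

* Single-class, single-channel segmentation only; no 2D mode.
* No resampling between spacings: masks are evaluated on their native
  grid, and volumes of different orientation conventions are taken as-is.
* The compute backend is a purpose-built CPU implementation (R with C++
  kernels); it is exact but not competitive with GPU frameworks at
  clinical matrix sizes (e.g. 576 x 576 x 88), where training at the
  published 200-epoch scale is out of reach for this package.
* The FLOP model is analytic (multiply-accumulates counted as 2
  operations); it reports per-shape totals and makes no attempt to match
  any particular published aggregate, whose input size is not stated.
* NRRD support covers attached-data scalar volumes (raw/gzip,
  little-endian) -- the subset produced by common segmentation tools.
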