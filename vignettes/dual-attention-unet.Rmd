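---
title: "A dual-attention U-Net for 2.5D hippocampus segmentation: model, protocol, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-attention U-Net for 2.5D hippocampus segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attunet)
```

## The problem

The hippocampus is a small, thin, crescent-shaped structure in the medial
temporal lobe whose atrophy is one of the earliest imaging biomarkers of
Alzheimer's disease. Delineating it on T1-weighted MRI is hard for exactly
the reasons that make it interesting: it occupies a tiny fraction of each
axial slice, its boundary contrast with neighbouring grey matter is weak,
and its appearance changes smoothly but substantially from slice to slice.
Fully 3D convolutional networks capture the volumetric context but are
heavy; plain 2D networks are light but treat each slice as if its
neighbours did not exist. This package implements a middle road — a 2.5D
approach: a 2D encoder–decoder segmenter whose predictions for slice
$i$ are informed by attention masks computed from slices $i-1$ and $i+1$.

## The network

The backbone is a five-level U-Net. Each encoder level applies two 3×3
same-padded convolutions with ReLU activations and then halves the spatial
dimensions with 2×2 max pooling; channel widths double per level
(32, 64, 128, 256, 512 in the reference configuration). On a 256×256×1
input the level outputs are 256×256×32, 128×128×64, 64×64×128, 32×32×256,
and a 16×16×512 bottleneck. The decoder mirrors this with 2×2 stride-2
transposed convolutions, concatenation of the matching encoder skip, and
two 3×3 convolutions per level, ending in a 256×256×32 feature map. A 1×1
convolution and a sigmoid produce the per-pixel foreground probability.

Two attention mechanisms are added:

* **Spatial attention (SA)**, at the bottleneck. Channel-wise max-pooling
  and average-pooling compress the 512-channel map into two 16×16
  descriptor planes; their 2-channel stack passes through one $k\times k$
  convolution ($k \in \{1,3,5,7\}$, default 3) and a sigmoid, giving an
  attention plane in $(0,1)^{16\times16}$ that gates every bottleneck
  channel multiplicatively. This is the channel-pooled spatial gate
  familiar from CBAM-style modules.

* **Inter-slice attention (ISA)**, at the decoder output. For slice $i$,
  the same lightweight operator (channel max+avg pooling → 3×3 convolution
  → sigmoid, with one shared set of weights for both neighbours) is applied
  to the final decoder feature maps of slices $i-1$ and $i+1$, yielding two
  masks $M_{prev}$ and $M_{next}$. The fused feature is
  $F_i \odot M_{prev} + F_i \odot M_{next}$, which then enters the 1×1
  sigmoid head. Because neighbouring slices of a real hippocampus overlap
  heavily, their attention masks highlight where foreground is plausible,
  enforcing volumetric consistency without 3D kernels.

Switching both modules off recovers the plain U-Net bit-for-bit, so the
four ablation variants (`unet`, `unet_sa`, `unet_isa`, `dual`) differ only
in configuration flags (`ablation_variants()`).

The reference configuration has 7,759,559 trainable parameters:

```{r params}
cfg <- unet_config()
count_parameters(cfg) / 1e6
head(parameter_table(cfg))
```

## Design choices where the architecture was genuinely open

Several details of this architecture family admit more than one reading;
the package fixes them as follows and records each as its own choice.

* **SA kernel bank.** The SA literature sometimes uses several kernel
  sizes in parallel. Here the module has a single configurable kernel,
  default 3×3 — the size that consistently wins in single-kernel ablations
  (`sa_kernel` in `unet_config()` exposes 1/3/5/7). A parallel multi-kernel
  bank would multiply SA parameters without changing its character; with
  the single 3×3 kernel the total parameter count lands at 7.76 M, which
  is consistent with the reference figure.
* **Decoder ordering.** Upsample → concatenate skip → dual convolution,
  the canonical U-Net ordering. Running the convolutions before
  concatenation would leave the skip channels unmixed at every level and
  break the usual shape accounting.
* **Upsampling operator.** 2×2 stride-2 transposed convolution by
  default; nearest-neighbour interpolation followed by a 1×1 convolution
  is selectable (`upsample_mode = "interp_plus_conv"`).
* **ISA internals.** Described in the field only as "lightweight"; this
  implementation reuses the SA operator structure with weights shared
  between the two neighbours. Sharing makes the module symmetric by
  construction (a mirrored volume produces mirrored masks) and keeps it at
  19 parameters.
* **ISA attachment point.** ISA consumes the pre-head decoder features of
  the slice triplet, and the 1×1 sigmoid head follows the fusion — so the
  final output remains a single-channel probability map.
* **Volume boundaries.** The first and last slice lack one neighbour;
  the default policy replicates the current slice into the missing
  position (`isa_boundary_policy = "replicate"`), zero-filling is
  selectable.
* **No normalization layers.** The reference configuration uses none;
  with per-slice min–max normalized inputs and He-uniform initialization
  the desk-scale networks train stably without them.
* **Initialization.** He-uniform for convolution weights
  ($\pm\sqrt{6/\text{fan-in}}$), zero biases, fully seed-controlled; two
  builds from the same configuration are bit-identical.
* **Binarization.** Threshold 0.5 with a strict inequality, so an
  exactly-0.5 probability is background. The sigmoid is clamped at logits
  ±30, keeping probabilities strictly inside (0,1) in double precision.

## Training protocol

`train()` optimizes mean binary cross-entropy with Adam (learning rate
0.001, framework-standard $\beta_1=0.9$, $\beta_2=0.999$), batch size 4,
for up to 200 epochs. Regularization follows the usual protocol for small
medical datasets: random horizontal and vertical flips applied identically
to image and mask (`augment_pair()`), CLAHE and Gaussian smoothing as
optional enhancement stages, early stopping on validation loss (default
patience 20), and reduce-on-plateau learning-rate decay (factor 0.5,
patience 10, floor 1e-5). The patience values and the plateau schedule are
this package's defaults — reasonable middle-of-the-road settings — since
only the optimizer, loss, rate, batch size and epoch budget are pinned by
the protocol itself. Validation subjects for early stopping are held out
of the training subjects (10% by default in the CLI); train/validation
subject leakage is rejected before training starts.

Slice sampling: volumes are dominated by empty slices (a 189-slice volume
may carry foreground on ~30). By default each subject contributes all
non-empty-mask slices plus an equal number of empty ones (seeded draw), so
the network sees both classes without drowning in background
(`balance_sampling`).

**Batching with ISA.** A training loss on slice $i$ depends on the decoder
features of $i-1$, $i$, $i+1$, all through the same weights. Batches are
therefore windows of (up to four) slice indices within one subject, and
each encoder–decoder pass the window touches is computed once and shared
by every loss that needs it; backpropagation runs through the neighbour
slices too. This is an exact-gradient evaluation strategy (verified
against central finite differences during development), not an
approximation — it merely avoids recomputing shared activations.

## Evaluation and statistics

`confusion_counts()` tallies TP/FP/TN/FN per slice; `compute_metrics()`
derives accuracy, precision, recall, F1, Dice and IoU. On any single
confusion matrix F1 and Dice are the same formula,
$2TP/(2TP+FP+FN)$, and Dice and Jaccard obey
$\mathrm{Dice} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$; reports can only show
F1 ≠ Dice through aggregation, which is why `aggregate_metrics()` exposes
both micro (sum counts, then compute) and per-slice-mean modes. Slices
where truth and prediction are both empty score 1 by default (a correctly
empty prediction is perfect), configurable to NA.

The primary aggregation is per-subject micro counts averaged across
subjects, which matches the statistics: `paired_t_test()` compares two
models' per-subject Dice/IoU with a two-sided paired t-test at
$\alpha = 0.05$ (sidedness is this package's choice; two-sided is the
conservative default), `confidence_interval()` gives t-distribution 95%
intervals, and `kfold_split()` produces subject-disjoint 5-fold
cross-validation partitions. Raw p-values are reported without
multiple-testing correction. Degenerate paired tests (zero variance of
differences) are signalled with a warning rather than silently patched.

## The synthetic phantom generator

Clinical hippocampus datasets are access-restricted, so the package ships
a generator whose volumes reproduce the *structure* of the task: per
subject, a stack of axial slices whose central band contains a small
bright crescent — the difference of two equal-radius offset discs, the
simplest shape with the concavity and thinness that make hippocampus
segmentation hard. The crescent's centre and orientation drift smoothly
from slice to slice (displacement uniform in [0, `drift_per_slice`]), so
adjacent masks overlap strongly and inter-slice attention has a real
signal to exploit. Images add smooth tissue texture, a low-order
multiplicative bias field emulating coil inhomogeneity generically, and
additive Gaussian noise, all clipped to [0,1]; masks are the exact
analytic crescent supports and are never perturbed.

Default parameters mirror a cross-sectional study layout (135 subjects ×
189 slices with a 30-slice labeled band at 256×256); the standard test
fixture (`fixture_benchmark()`) scales this to 20 subjects × 12 slices at
64×64 with a 6-slice band, crescent outer radius 10–12 px, thickness
3.5–4.5 px, drift 0.8 px/slice, noise SD 0.05, bias amplitude 0.1, seed 7,
split 16 training / 4 test subjects. At these settings foreground covers
roughly 2% of in-band pixels — the small-structure regime — adjacent-slice
mask Dice stays above 0.7, an untrained model scores near zero, and a
width-8 network trains to high Dice in minutes on one CPU, giving the test
suite headroom on both sides.

What passing on phantoms does and does not show: the phantoms exercise
shape recovery, class imbalance, inter-slice coherence, intensity
inhomogeneity and noise, but not true anatomical variability, partial
volume effects, scanner protocol differences, or ambiguous boundaries.
Desk-scale results on phantoms validate the implementation and the
protocol, not clinical performance.

## Problem sizes used by the shipped checks

All checks run on one CPU. The architecture-level checks (parameter count,
shape schedule) use the full 256×256 reference configuration, since a
single forward pass is cheap. Learning checks use the 64×64 fixture with
width-8 networks: the held-out benchmark trains the dual-attention variant
for up to 30 epochs (reaching subject-averaged Dice ≈ 0.95 on the four
test subjects), and the overfit-one-batch check drives BCE on four slices
below 0.05 within 200 Adam steps. Metric and statistics checks use
closed-form hand computations and thousand-pair random-mask sweeps.

## Numerical notes and limitations

* Convolutions use zero same-padding everywhere, so printed shapes hold
  exactly; inputs must be divisible by $2^{\text{depth}-1}$ (arbitrary
  sizes are handled by the zero-pad / crop-back round trip, which is
  exact by construction).
* All kernels run in double precision via im2col + GEMM (RcppArmadillo);
  SA/ISA toy tensors match explicit-loop oracles to well below 1e-5.
* Max-pooling ties (exactly equal values in a 2×2 window) route gradients
  to the first maximum in column-major order; ties are measure-zero for
  continuous inputs.
* The engine is CPU-only and single-threaded by design of the
  environment; wall-clock figures from GPU implementations are out of
  scope, as are pretrained weights, 3D-kernel variants, multi-class
  subfield labels, and surface-distance metrics.
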