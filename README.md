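# attunet

A dual-attention U-Net for 2.5D hippocampus segmentation in brain MRI,
implemented natively in R (all tensor kernels in C++ via RcppArmadillo —
no external deep-learning framework).

The hippocampus is a small crescent-shaped medial-temporal structure whose
atrophy is an early Alzheimer's biomarker. Segmenting it on axial
T1-weighted slices is a small-foreground problem (~1–3% of pixels) with
strong slice-to-slice continuity. `attunet` implements a five-level
encoder–decoder network with two attention mechanisms:

* a **spatial attention (SA)** gate at the 16×16×512 bottleneck — channel
  max/avg pooling → one k×k convolution (default 3×3) → sigmoid → a
  per-pixel gate in (0,1) multiplied onto every channel;
* an **inter-slice attention (ISA)** module at the decoder output — masks
  computed from the neighbouring slices' decoder features
  (shared-weight channel-pool → 3×3 conv → sigmoid), fused as
  `F_i ⊙ M_prev + F_i ⊙ M_next` before the 1×1 sigmoid head, injecting
  volumetric context into a 2D network.

Around the model the package ships the full experimental protocol:
zero-pad/crop-back preprocessing with CLAHE and Gaussian denoising, paired
flip augmentation, confusion-matrix metrics (accuracy, precision, recall,
F1, Dice = 2TP/(2TP+FP+FN), IoU = TP/(TP+FP+FN)), subject-level k-fold
splits with paired t-tests and 95% confidence intervals, an Adam/BCE
training engine (lr 0.001, batch 4, early stopping, plateau LR decay), a
four-way ablation harness (U-Net / +SA / +ISA / dual), and a synthetic
phantom generator so everything is testable without clinical data.

## Worked example

The reference configuration reproduces the published architecture
exactly — five encoder levels of width 32 doubling to 512 on a 256×256×1
input, 3×3 SA kernel, ISA enabled:

```r
library(attunet)
cfg <- unet_config()
count_parameters(cfg) / 1e6
#> [1] 7.759559        # ~7.76 M trainable parameters
```

Train the dual-attention variant on the built-in phantom benchmark
(20 subjects × 12 slices at 64×64, width-8 network; ~8 min on one CPU):

```r
ds    <- fixture_benchmark()
split <- dataset_split(ds, n_val = 2L, seed = 1L)   # 14 train / 2 val / 4 test
cfg   <- unet_config(input_height = 64L, input_width = 64L,
                     base_channels = 8L, seed = 1L)
fit   <- train(cfg, split$train, split$val,
               train_config(max_epochs = 30L, seed = 1L))
evaluate(fit, split$test)
#>   accuracy precision   recall       f1     dice      iou
#> 1 0.999008  0.974316 0.939983 0.956336 0.956336 0.916716
#>               aggregation n_slices n_subjects
#> 1 per_subject_mean(micro)       48          4
```

Held-out-subject Dice ≈ 0.96: the network recovers the drifting crescents
almost perfectly on subjects it never saw. `autoplot(fit$log)` draws the
loss/Dice curves; `plot_slice(img, mask, pred)` overlays contours on a
slice. A command-line interface wrapping the same functions is installed
at `system.file("cli", "attunet", package = "attunet")` with subcommands
`simulate | train | evaluate | predict | ablate | params`.

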