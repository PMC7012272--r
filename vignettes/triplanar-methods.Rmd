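---
title: "Tri-planar multichannel CNNs for task fMRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tri-planar multichannel CNNs for task fMRI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Task-evoked fMRI records a time series of 3D brain volumes while a
participant performs cued actions in timed blocks. In the motor task the
cues are five movements — left hand, right hand, left foot, right foot,
tongue — performed twice each in ten movement blocks, with three fixation
(rest) blocks intermixed. The classification problem is: given the BOLD
signal of one movement block, predict which movement was performed.

`triplanar` implements the full pipeline for this problem: collapsing each
movement block to a single labeled 3D image, transforming that image into
the input representation of one of six network families, and training and
evaluating the networks under subject-wise cross-validation. A synthetic
motor-task generator stands in for real scans so that every step is
runnable and testable offline.

## From blocks to samples

**Baseline.** All frames of all fixation blocks are pooled, and each
voxel's baseline $\bar y$ is its mean over those frames. Pooling (rather
than per-block baselines) is used because a single per-voxel baseline map
is what the block-collapsing statistic below consumes.

**Mean percent signal change.** A movement block with frames
$y_1, \dots, y_N$ at a voxel is collapsed to

$$p = \frac{\sum_{i=1}^{N} y_i}{\bar y \cdot N} \cdot 100,$$

the block mean as a percentage of baseline. Note the ratio form: a block
identical to baseline scores $p = 100$, and an $a\%$ activation scores
$100 + a$. The more common centered convention $(\bar{y}_{block}-\bar
y)/\bar y \cdot 100$ differs only by the constant 100; it is available as
`convention = "centered"` in `mean_psc()` / `extract_samples()` but the
ratio form is the default because it is the form the downstream models
were specified with. Since the per-voxel normalization below subtracts the
voxel mean anyway, the two conventions produce identical model inputs.

**Degenerate baselines.** Masked scans have exact zeros outside the brain,
where $p$ is undefined. Voxels with $|\bar y| < 10^{-8}$ are set to 0 and
flagged in a returned mask attribute rather than propagating infinities.

**Normalization.** Each voxel is z-scored across samples (subtract the
voxel mean, divide by the voxel standard deviation). The population
(divide-by-$n$) standard deviation is used; at realistic sample counts the
difference from $n-1$ is immaterial, but one choice has to be fixed for
exact testability. Two fitting modes exist: `all_samples` (statistics over
the full dataset, the protocol the harness reproduces by default) and
`train_only` (statistics from the training fold applied to validation and
test folds). The first mode lets test data influence the statistics; the
second is the leakage-free variant, and a test in the suite verifies that
under `train_only` perturbing test samples cannot change the training
trajectory.

## Input representations

All transforms address array axes by position (axes 1, 2, 3); anatomical
plane names are deliberately avoided in code because the mapping of
coronal/sagittal/axial onto array axes varies across conventions. For a
volume of shape $(d_1, d_2, d_3)$:

* **tri-planar** (`m2d`): three multichannel 2D images, obtained by
  slicing along each axis and stacking the slices as channels —
  $(d_2, d_3)$ with $d_1$ channels, $(d_1, d_3)$ with $d_2$ channels,
  $(d_1, d_2)$ with $d_3$ channels. Each stack is a pure axis permutation
  and reconstructs the volume exactly.
* **single-plane** (`s2d`): only the third-axis stack.
* **mean-value** (`mv2d`): the third axis collapsed by averaging — the one
  lossy representation.
* **sequence** (`conv1d`): the $d_3$ slices concatenated along axis 2 into
  a sequence of length $d_2 d_3$ with $d_1$ features per step (axis 2
  varies fastest). For $91 \times 109 \times 91$ this gives 9,919 steps of
  91 features.
* **volumetric** (`conv3d`, `conv3d_sep`): the raw single-channel 3D
  volume.
* **flattened** (`pca_svm`): the $d_1 d_2 d_3$ voxel vector (column-major
  order, fixed and documented).

## The six network families

Every family shares one trunk: two convolution layers of 16 and 32 kernels
of size 3 per spatial dimension, valid padding (no padding), each followed
by leaky-ReLU (negative slope 0.3), max pooling of size 2 (stride 2,
dimensions floor-halved) and batch normalization; then flatten — for the
tri-planar model, concatenation of the three branch flattens into one
merge vector — dropout of 50%, a dense layer of 128 units with leaky-ReLU
and batch normalization, and a dense softmax output over the 5 classes.
Training minimizes categorical cross-entropy.

Two conventions deserve comment because they are the ones that make the
closed-form accounting come out exactly:

* **Valid padding and floor pooling.** Each conv shrinks a spatial extent
  by 2, each pool floor-halves it: $d \mapsto \lfloor (d-2)/2 \rfloor$
  per stage. At $91 \times 109$ this yields $21 \times 25 \times 32 =
  16{,}800$ flatten units, at $91\times109\times91$ it yields 352,800, and
  on the 9,919-step sequence 79,296; the tri-planar merge vector is
  $16{,}800 + 14{,}112 + 16{,}800 = 47{,}712$. These are the unique
  padding/pooling conventions consistent with all of those counts
  simultaneously.
* **Normalization placement.** Besides the per-channel normalization after
  each pool, the 1D/2D families carry a per-feature normalization of the
  flatten/merge vector, and all families carry one after the dense 128
  layer; the 3D families have no post-flatten normalization. Each
  normalized feature contributes 4 parameters (scale, shift, running mean,
  running variance — the running statistics are counted although they are
  not trained). This placement is the unique one under which the
  closed-form totals of all six families match their reference values
  exactly; it is encoded in `arch_config()` and cross-checked against
  built models by `verify_counts()`.

The separable 3D variant (`conv3d_sep`) replaces only the second
convolution with a depthwise $3^3$ stage (depth multiplier 1, no bias)
followed by a pointwise $1^3$ stage (with bias), saving exactly
$(27 \cdot 16 \cdot 32 + 32) - 27 \cdot 16 - (16 \cdot 32 + 32) =
12{,}880$ parameters. The bias split is forced by that difference: any
other assignment of biases changes it.

### The engine

No deep-learning framework is assumed: the package carries its own
minimal engine (n-dimensional valid convolution via im2col and BLAS
matrix products, depthwise/pointwise convolution, max pooling with
first-occurrence tie-breaking, batch normalization with running
statistics, inverted dropout, dense layers, Adam). Backpropagation through
every layer is verified against central finite differences in the test
suite. Batch normalization uses $\varepsilon = 10^{-3}$ and momentum 0.9
for the running statistics; weights are initialized with the uniform
fan-in/fan-out rule and biases at zero. Convolution layers that sit
directly on the input skip the (never consumed) input-gradient
computation.

## Training protocol

* **Optimizer:** Adam, initial learning rate 0.0025, halved every 50
  epochs (`lr_at_epoch()`).
* **Checkpointing:** after every epoch the model is evaluated on the
  validation set; the epoch with the best validation accuracy is kept
  (ties to the earliest epoch). `select = "loss"` switches the criterion
  to validation loss — the protocol's "best validation result" is ambiguous
  between the two, and accuracy is the headline metric, so it is the
  default.
* **Early stopping:** training stops when the training loss has not
  dropped below its running minimum for 6 consecutive epochs (strict
  improvement, tolerance 0). A constant loss stream therefore stops after
  1 + 6 epochs: the first epoch sets the floor, six stalled epochs
  trigger the rule.
* **Batch size:** 32 by default (the protocol leaves it unstated; the
  value is recorded in run metadata by the CLI).
* **Cross-validation:** subjects, not samples, are split into k folds, so
  all 10 samples of a subject land in the same partition. Per fold, the
  test fold is ~1/k of subjects; 10% of the remaining subjects are
  validation, the rest training. All randomness (split, initialization,
  shuffling, dropout) derives from the run seed.
* **Metrics:** accuracy, macro-averaged precision and macro-averaged F1
  (classes are balanced by design, where macro and micro nearly coincide;
  macro is fixed for determinism), plus the full confusion matrix.

The PCA+SVM baseline projects the flattened voxel vectors onto the top
500 principal components fit on the training fold (clamped with a warning
when fewer are available) and trains a linear SVM with $C = 1$.

## The synthetic generator

`synth_config()` emulates the motor-task block structure: 3 fixation
blocks at the start, middle and end, with the 10 movement blocks (2 per
class, order shuffled per subject) in between, all of equal length. The
anatomy is a soft-edged ellipsoid "brain" of peak baseline 1000 inside an
otherwise exactly-zero background — mimicking masked real volumes and
deliberately exercising the zero-baseline guard. Each class activates one
sphere of radius 3 voxels at a fixed centre; the five centres differ along
all three axes so that every slicing plane carries class information.
Movement frames are multiplied by $1 + a/100$ inside the class ROI;
Gaussian noise of standard deviation $\sigma$ (scanner units) is added per
frame per voxel inside the brain mask; each subject's whole baseline is
scaled by a log-normal multiplier (sd 0.1 on the log scale) to create
between-subject variation.

Defaults are `dims = c(24, 28, 24)`, 12 frames per block, $a = 30$,
$\sigma = 1$, seed 7. The grid is deliberately far below scanner
resolution so that a full 20-subject, 5-fold cross-validated run of the
tri-planar model completes in minutes on one CPU; the full-resolution
$91 \times 109 \times 91$ shape is used only for parameter accounting,
which builds models but never trains them. With $a = 30$ and $\sigma = 1$
the activation is enormous relative to the post-collapse noise
($\approx 0.03$ percent-signal-change units), so the classes are cleanly
separable — the regime verifies that the pipeline learns, not that it is
robust. With $a = 0$ there is no signal at all and every classifier must
sit at the 20% chance level; both regimes are asserted in the test suite.

What the generator does **not** model: hemodynamic response dynamics
(activation is a step function of the block), physiological and motion
artifacts, spatial autocorrelation of noise, partial-volume effects, and
inter-subject anatomical variability beyond a global intensity
multiplier. Passing tests on synthetic data therefore demonstrate the
correctness of the pipeline's computations and the learnability of
block-localized spatial signal — not performance on real scans.

## Numerical and degenerate-input choices

* Frame indexing is 0-based with half-open blocks $[s, s+n)$; schedules
  are validated against overlap and overrun, and labels against the fixed
  six-label vocabulary.
* `conv_stack_units()` and `build_model()` refuse inputs whose spatial
  extent collapses below 1 anywhere in the stack (the minimum viable
  extent is 11 with the default kernel/pool sizes).
* Max pooling breaks ties by first occurrence; softmax is max-shifted;
  cross-entropy clips probabilities at $10^{-12}$.
* A training batch whose loss turns non-finite aborts with a typed error
  rather than continuing silently.
* Sample containers are persisted as a single serialized file holding the
  volume array, labels and subject ids; round trips are bit-exact.

## Known limitations

* The engine is CPU-only and written for clarity and desk-scale problems;
  training at full scanner resolution is out of its intended range
  (parameter accounting at that scale is instant, building is cheap,
  training is not).
* The running batch-normalization statistics are momentum estimates; with
  very few training steps they lag the batch statistics, which can depress
  inference-mode accuracy on tiny runs.
* `pca_svm` uses a dense SVD; at full resolution the flattened feature
  matrix is large and the decomposition is the memory bottleneck.
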