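---
title: "Attention-gated residual networks for MCI detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-gated residual networks for MCI detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mild cognitive impairment (MCI) is the transitional state between normal
aging and Alzheimer's disease. On structural MRI its signature is subtle:
localized atrophy in small regions (hippocampus and nearby structures),
embedded in a large volume that is mostly irrelevant to the decision.
`mcigate` implements a 3D convolutional classifier built for exactly this
regime: a residual backbone provides depth without vanishing gradients, an
*attention gate* suppresses the (large) irrelevant background, and
*parallel dilated convolution* (atrous spatial pyramid pooling, ASPP)
enlarges the receptive field around the small lesion targets without
further downsampling.

The intended input is a preprocessed gray-matter probability map —
skull-stripped, tissue-segmented, registered to a common template — on a
canonical grid of 84 × 102 × 84 voxels, together with a cohort manifest
that groups longitudinal scans by subject. Because suitable clinical data
are access-restricted, the package ships a phantom simulator that
reproduces the *structure* of such a cohort and makes every downstream
claim testable.

## The model

**Backbone.** An 18-layer 3D residual network: a 3×3×3 stem convolution
(batch norm, ReLU, 2× max-pool), then four stages of two residual blocks
each (conv–BN–ReLU–conv–BN plus identity shortcut, ReLU after the
addition), with stage widths 1×, 2×, 4×, 8× `base_channels` and stride-2
downsampling entering stages 2–4. Batch normalization is part of the
residual-block definition used here; with small batches its evaluation
statistics are re-estimated after every epoch by a full pass over the
training fold ("precise BN"), because the exponentially-averaged statistics
tracked during optimization are otherwise too noisy to support
evaluation-mode inference (see *Numerical choices*).

**Attention gate.** For a local feature map $x^l$ (stage 2 or 3) and the
deepest feature map $g$ (stage 4) used as gating signal, the gate computes
per-position coefficients

$$q_i = \psi^\top \sigma_1\!\left(W_x^\top x_i + W_g^\top g_i + b_{xg}\right) + b_\psi,
\qquad \alpha = \sigma_2(q),$$

with $\sigma_1$ = ReLU and $\sigma_2$ a softmax over the spatial positions
of a sample, so the coefficients sum to one (an elementwise sigmoid is
available via `sigma2 = "sigmoid"`; softmax-normalized coefficients shrink
with grid size, which is the main reason to offer the alternative). All
three maps are 1×1×1 convolutions. The additive terms must share a grid:
$x^l$ is brought to $g$'s grid by a strided 1×1×1 projection (stride
⌈dim ratio⌉ per axis, followed by an exact adaptive average pool when the
strides do not land exactly), the coefficients are computed there, and
$\alpha$ is trilinearly resampled back to $x^l$'s grid before the
multiplicative gating $\hat x^l_i = \alpha_i x^l_i$. Ψ maps to a single
channel, so there is one coefficient per spatial location, broadcast over
channels.

**Dilated convolution and ASPP.** A kernel with $k$ taps per side and
dilation rate $d$ covers an effective side of $k + (k-1)(d-1)$ without
extra parameters. The ASPP block runs one 3-tap dilated branch per
configured rate (default rates 1, 2, 3) plus a 1×1×1 branch, concatenates
the branch outputs along channels, and projects back with a 1×1×1
convolution; spatial dimensions are unchanged throughout. Branches are
linear (no normalization inside the block); the nonlinearity sits in the
fusion stage that follows.

**Wiring and variants.** `baseline` global-average-pools stage 4 into a
two-class linear classifier. `ag` gates stages 2 and 3 with $g$, pools the
gated maps to $g$'s grid, concatenates them with $g$, projects 1×1×1
(BN, ReLU), pools, classifies. `ag_aspp` additionally passes each gated map
through its own ASPP block before the fusion. The three variants form the
ablation ladder; parameter counts are strictly nested.

**Initialization.** All convolution and fully connected weights are drawn
truncated-normal with sd `init_sd` (default 0.1; the truncation resamples
outside ±2 sd). Biases start at zero; BN starts at identity.

## Training regime

Two-class cross-entropy, Adam (default; SGD, momentum, RMSprop
selectable), batch size 8, base learning rate 0.001 decayed by ×0.1 every
10 epochs, 50 epochs at full scale. A subject-level validation fraction
(default 0.2) is carved from the training cohort; the checkpoint with the
best validation accuracy is kept, ties resolved toward the earlier epoch.
Every stochastic component — initialization, shuffling, augmentation noise,
phantom draws — derives its stream from one seed via a deterministic
string-hash, so any run is exactly reproducible and any subject's volume
can be regenerated in isolation.

## The phantom generator

The generator emulates the structure of a longitudinal two-class cohort,
not brain anatomy:

- a smooth background template (a fixed superposition of anisotropic
  Gaussian bumps, rescaled to peak 0.85) shared by all subjects;
- a per-subject multiplicative gain $1 + \mathcal N(0, \texttt{subject\_effect\_sd})$
  (default 0.1), constant across a subject's scans — this creates the
  within-subject correlation that makes subject-level splitting matter;
- two mirrored pairs of small ellipsoidal lesions at hippocampus-adjacent
  loci (radii 7% of each axis, at least 2 voxels), inside which class-1
  intensity is multiplied by `atrophy_factor` (default 0.6);
- i.i.d. voxel noise (`noise_sd`, default 0.05), then a clamp to [0, 1]
  since gray-matter probability maps are bounded.

What passing tests on phantoms do show: the architecture can learn a
localized, small-volume intensity contrast from subject-split data, the
pipeline is leakage-free, and Grad-CAM concentrates on the true lesion
sites. What they do not show: robustness to registration error,
scanner/site effects, anatomical variability, or the far weaker effect
sizes of real MCI — phantom accuracies are far above anything attainable
on clinical data.

## Desk-scale study sizes

The full-scale configuration (84 × 102 × 84, `base_channels = 64`,
50 epochs, 25× augmentation) is a GPU-scale computation. The package's
own reference study — what `demo_config()` runs and what the test suite
exercises end-to-end — uses a 32 × 40 × 32 grid, 40 subjects per class
with one scan each, `base_channels = 8`, 10 epochs, no augmentation, and
a 75/25 subject split. These sizes were fixed once as the desk-scale
conditions; on them the attention + ASPP variant reaches held-out accuracy
near 1.0 on 20 test scans, so variant comparisons at this scale are
dominated by binomial noise and are read only as non-inferiority checks,
never as effect-size estimates. The ablation comparison holds the subject
split fixed and varies only training randomness (seeds 0–2 per variant),
mirroring how ablation tables hold the data constant while modules change.

## Numerical choices

- **Precise BN.** With batch 8 and deep stages whose spatial grid is only
  ~12 voxels, per-batch normalization statistics fluctuate strongly;
  models trained this way can show near-chance evaluation-mode accuracy
  on their own training data when normalized by exponentially averaged
  statistics. After each epoch the running statistics are therefore
  replaced by the arithmetic average of batch statistics over one pass of
  the training fold. This is a pure re-estimation: weights are untouched.
- **Softmax shift invariance.** The spatial softmax makes the gate's
  output bias $b_\psi$ unidentifiable (adding a constant to $q$ leaves
  $\alpha$ unchanged), so its gradient is exactly zero in softmax mode.
  The parameter is kept for the sigmoid configuration, where it is active.
- **Dilated convolution** uses zero "same" padding of $(k_{\mathrm{eff}}-1)/2$
  per side, so rate 1 reproduces ordinary convolution exactly and spatial
  dimensions never change; inputs smaller than the effective kernel are
  rejected rather than silently over-padded.
- **Trilinear resampling** uses the half-voxel center convention with
  edge clamping; its adjoint (exact transpose) is used in the backward
  pass, so gradient checks pass to machine precision.
- **Metrics with empty denominators** (e.g. precision when nothing is
  predicted positive) are reported as `NaN` with a warning rather than 0,
  so fold averages cannot be silently dragged down.
- **Ties in ROC** are handled by grouping equal scores at one threshold;
  the trapezoidal area then equals the rank-statistic (pair-counting)
  estimator including half-credit for ties.
- **Grad-CAM layer.** `grad_cam()` defaults to the deepest stage. The
  desk-scale demo reads saliency at stage 2 instead: after four
  downsamplings of a 32 × 40 × 32 grid the deepest stage is 2 × 3 × 2 —
  coarser than the lesions — while the finest gated stage resolves them
  (its localization scores are correspondingly higher). Lesion-evidence
  maps are computed on volumes of the mapped class; on a control volume
  a well-trained model may output no positive class-1 evidence at all,
  making the score undefined there.
- **Augmentation catalogue.** The 25-fold expansion is: identity, 3
  single-axis flips, 12 rotations (±5°, ±10° about each axis, trilinear,
  zero-padded — gray matter is zero outside the head), and 9 seeded
  additive-noise variants (sd 0.01/0.02/0.03 × 3 draws). The count
  includes the original as entry 1. Augmentation applies to training data
  only, after splitting; augmenting before the split would leak.
- **Split rounding.** Per-class test subjects = `round(fraction × n)`,
  minimum 1, so class balance survives small cohorts.

## Known limitations

- Phantoms are structurally, not anatomically, realistic; no
  preprocessing chain (skull stripping, segmentation, registration) is
  simulated, and the package does not ingest raw T1w images.
- Training is CPU-bound and single-threaded apart from BLAS; full-scale
  (84 × 102 × 84, width 64) training is out of desk reach.
- The compute engine implements exactly the operations this architecture
  needs; it is not a general-purpose autodiff framework.
- Checkpoint weight archives are R serialization files; the paired YAML
  config is the portable description.
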