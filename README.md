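# mcigate

Detection of mild cognitive impairment (MCI) from 3D gray-matter MRI with
an attention-gated residual network and parallel dilated convolution —
implemented end-to-end in R with its own compiled 3D convolution /
reverse-mode differentiation engine, and exercised on synthetic
gray-matter phantoms with known lesion geometry.

## The problem and the model

MCI, the transitional state between normal aging and Alzheimer's disease,
shows on structural MRI as subtle, highly localized atrophy inside a large
and mostly uninformative volume. `mcigate` classifies preprocessed
gray-matter probability maps (canonical grid 84 × 102 × 84) with a 3D
ResNet-18-style backbone augmented by two mechanisms aimed at small,
localized targets:

- **Attention gates.** With a local feature map *x*<sup>*l*</sup> (stage 2
  or 3) and the deepest feature map *g* as gating signal, per-position
  coefficients are computed as

  *q*<sub>i</sub> = ψᵀ ReLU(W<sub>x</sub>ᵀ x<sub>i</sub> + W<sub>g</sub>ᵀ g<sub>i</sub> + b<sub>xg</sub>) + b<sub>ψ</sub>,  α = σ₂(q),

  with σ₂ a softmax over the spatial positions of each sample (Σα = 1),
  and the gated output α ⊙ x<sup>*l*</sup> suppressing irrelevant regions.
- **Parallel dilated convolution (ASPP).** A kernel with *k* taps per side
  at dilation rate *d* covers an effective side of *k* + (*k*−1)(*d*−1);
  parallel branches at rates {1, 2, 3} are channel-concatenated and
  projected, enlarging the receptive field around small lesions without
  downsampling.

Three variants form an ablation ladder: `baseline` (plain backbone), `ag`
(+ attention gates), `ag_aspp` (+ ASPP on the gated maps). Training
follows the regime: Adam, batch 8, learning rate 0.001 decayed ×0.1 every
10 epochs, truncated-normal init (sd 0.1), subject-level validation with
best-checkpoint selection. Evaluation reports SEN/SPE/ACC/F1 from the
confusion matrix, AUC from the ROC curve, and subject-level k-fold
cross-validation. Grad-CAM produces volumetric saliency maps, and a
lesion-localization score (mean saliency inside the lesion mask over mean
outside) quantifies whether the model looks at the right place.

Because clinical data are access-restricted, the package includes a
phantom module generating two-class cohorts — smooth anatomical
background, per-subject gain shared across longitudinal scans, small
ellipsoidal lesions with a multiplicative atrophy contrast, voxel noise —
so the whole pipeline is testable and exactly reproducible from one seed.

## Worked example

The demo configuration is the package's desk-scale reference study:
40 phantom subjects per class on a 32 × 40 × 32 grid (atrophy factor 0.6,
voxel noise 0.05), a 75/25 subject split, and the `ag_aspp` variant at
base width 8 trained for 10 epochs.

```r
library(mcigate)
res <- run_pipeline(demo_config(out_dir = "demo_run", seed = 0))
res$report$metrics
#> $SEN
#> [1] 1
#> $SPE
#> [1] 1
#> $ACC
#> [1] 1
#> $F1
#> [1] 1
#> $AUC
#> [1] 1
res$median_localization
#> [1] 2.600741
```

All 20 held-out scans (10 per class) are classified correctly — the
phantom contrast is deliberately strong — and the median Grad-CAM
localization score of 2.60 means mean saliency inside the true lesion
mask is about 2.6 times the mean outside, i.e. the network's evidence
concentrates on the lesioned region it was never told about. The run directory
contains the split manifests (`train.tsv`, `test.tsv`), per-epoch
`history.tsv`, the checkpoint (weights + model YAML), `report.json` with
counts/metrics/ROC, and CAM volumes under `cams/`.

Individual stages are exported (`generate_cohort()`, `subject_split()`,
`augment_volume()`, `build_model()`, `train()`, `evaluate_cohort()`,
`cross_validate()`, `grad_cam()`), and `inst/cli/mcigate.R` is a thin
command-line wrapper with matching subcommands (`simulate`, `split`,
`augment`, `train`, `evaluate`, `gradcam`, `demo`, `run`).

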