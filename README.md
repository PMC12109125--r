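# bcrformer

Preoperative prediction of **biochemical recurrence** (BCR) of prostate
cancer — two consecutive post-prostatectomy PSA measurements ≥ 0.2 ng/mL —
from multiparametric MRI and clinical covariates. The package is aimed at
imaging researchers who have co-registered T2-weighted (fat-suppressed)
and diffusion-weighted volumes with tumor and prostate segmentations, and
want a tested, end-to-end implementation of multi-region /
multi-sequence CNN–transformer fusion, including the evaluation
statistics and a synthetic phantom generator so every stage can be
exercised without patient data.

## The model

Three anatomical regions are built from the segmentations by
millimetre-exact morphological dilation (anisotropic voxel spacing
respected):

| Region | Definition |
|---|---|
| ITR | intratumoral region: the tumor mask |
| PTR | peritumoral region: 5 mm shell around the tumor, clipped to the prostate |
| PPR | periprostatic region: 5 mm shell outside the prostate, adjacent organs excluded |

Per axial slice, the two sequences form a dual-channel masked image
`I ∈ R^{W×H×2}`. A shared CNN encoder (ResNet-18 scale, or a small
residual backbone for CPU work) maps each slice to
`f_image ∈ R^{W_I×H_I×C_I}`; a learned axial-position plane is added
(`f_ASI = f_as + f_image`); region features are concatenated along
channels, and the clinical vector — numeric covariates min–max scaled to
[0, 1], ordinal covariates coded `(k−1)/(K−1)` — is linearly embedded and
replicated over the `W_I×H_I` plane, giving
`f_combination ∈ R^{W_I×H_I×C_total}`. Its `S = W_I·H_I` channel-dimension
tokens pass through a transformer encoder; the pooled output yields a
slice recurrence value `r_i = W_FC·TransformerFeatureEncoder(f_comb) + B_FC`,
and a final FC + sigmoid over `R = (r_1…r_N)` gives the patient
probability `ŷ`, trained with binary cross-entropy
`−(1/N) Σ [y log ŷ + (1−y) log(1−ŷ)]`.

Training follows the standard protocol: AdamW (lr 1e-4, decoupled weight
decay), cosine annealing, batch 16, early stopping on validation AUC
(patience 10), augmentation (flip/rotation/brightness/contrast), and
stratified resampling — an 80/20 largest-remainder split and 5-fold
cross-validation repeated 20 times. Evaluation: sensitivity, specificity,
accuracy, F1, tie-aware Mann–Whitney AUC, percentile CIs over
fold-repeat estimates, and the DeLong test for correlated ROC curves.

There is no deep-learning framework dependency: the network layers
(convolution, batch norm, pooling, multi-head attention, layer norm) and
reverse-mode gradients are implemented in the package on Rcpp/Armadillo
kernels, and verified against finite differences in the test suite.

## Worked example

A full desk-scale experiment on synthetic phantoms (60 patients, tiny
backbone, 3-fold CV — a few minutes on one CPU):

```r
library(bcrformer)

rec <- run_experiment(list(
  variants = c("ITR", "Combined", "Clinical"),
  simulate = list(n_patients = 60, prevalence = 0.2),
  train    = list(lr0 = 2e-3, batch_size = 16, max_epochs = 15,
                  patience = 10, weight_decay = 0.01, k = 3, repeats = 1,
                  rotation_deg = 0, flip_prob = 0.5,
                  brightness = 0.1, contrast = 0.1)),
  seed = 1, out_dir = "runs/demo")
rec$comparison
```

```
Model comparison (reference: Combined )

    model            accuracy                 auc                  f1
 Clinical 0.601 (0.321-0.786) 0.460 (0.372-0.557) 0.211 (0.015-0.332)
 Combined 0.867 (0.850-0.893) 0.923 (0.816-0.998) 0.383 (0.020-0.733)
      ITR 0.885 (0.850-0.943) 1.000 (1.000-1.000) 0.509 (0.036-0.796)
         sensitivity         specificity
 0.444 (0.017-0.967) 0.645 (0.211-0.882)
 0.417 (0.013-0.963) 0.958 (0.881-1.000)
 0.556 (0.033-0.983) 0.941 (0.832-1.000)

DeLong tests vs Combined
  model_a  model_b auc_a auc_b          z            p band
 Combined      ITR 0.874 0.870 0.03275589 0.9738692541   ns
 Combined Clinical 0.874 0.462 3.39858325 0.0006773585  ***
```

Read: each row summarizes one model variant's cross-validated metrics
(mean and 95% percentile CI over the three folds). The phantom generator
plants its strongest label-dependent effect inside the tumor, so at this
small cohort size the intratumoral and combined models both learn the
task (their pooled ROC curves are statistically indistinguishable, DeLong
p = 0.97) while both dominate the clinical baseline (p < 0.001); wide CIs
are what 20-patient validation folds look like. Artifacts (predictions,
per-fold histories, fold plan, metric report, DeLong table, config
snapshot, log) land under `runs/demo/`.

Smaller building blocks are ordinary functions:

```r
pp  <- phantom_params(n_patients = 1, seed = 7)
ph  <- generate_phantom(pp, label = 1)
rs  <- build_regions(ph$tumor, ph$prostate, ph$exclusion, margin_mm = 5)
dice(rs$itr, ph$tumor)                       # 1
sl  <- extract_slices(zscore_normalize(ph$t2), zscore_normalize(ph$dwi),
                      rs$itr, slice_opts(n_slices = 8, input_size = 64))
m   <- init_model(desk_config(regions = "ITR"), seed = 1)
forward_patient(m, list(slices = list(ITR = sl)), "P001")
```

A thin CLI wraps the same functions:
`inst/cli/bcrformer simulate|build-rois|run --config ... --seed ...`.

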