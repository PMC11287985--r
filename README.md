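# fuseseg

Early, intermediate and late data fusion for CNN-based segmentation of
clinically significant prostate cancer (csPCa) lesions from
multiparametric-MRI-like volumes plus scalar clinical covariates — as a
fully tested, desk-scale R pipeline exercised end to end on synthetic
phantom cohorts.

## Who this is for

Researchers who want to study *where* to fuse heterogeneous inputs in a
segmentation network — at the input (EF), at the bottleneck features (IF),
or at the decision level (LF) — with a pipeline whose every stage
(simulation, preprocessing, patching, training, evaluation, statistics) is
reproducible and unit-tested, without access to any clinical dataset.

## The models

All three fusion families share one baseline: a patch-based 3D U-Net with 3
encoder and 3 decoder blocks, instance normalization, ReLU, 2×2×2 max
pooling, skip connections, and a voxelwise sigmoid output
p(lesion) ∈ [0, 1].

* **EF** — clinical scalars (PSA, PSAD, gland volume, GTV) are broadcast to
  constant channels and stacked with T2W/ADC/high-b into a 7-channel input
  (channels 1–3 mpMRI, 4–7 clinical).
* **IF** — one single-channel encoder head per mpMRI volume plus a 3-layer
  MLP on the clinical vector; features concatenate at the bottleneck (and
  per-level head features feed the shared decoder's skips).
* **LF** — three independent single-channel U-Nets plus a clinical MLP
  producing a patient-level lesion-probability scalar; the prediction is
  the arithmetic mean of member probability maps:
  p = (p_T2W + p_ADC + p_highb + p_clin) / 4.

Evaluation uses the Dice–Sørensen coefficient
DSC = 2|A∩B| / (|A|+|B|), voxel precision/recall, F1 = 2PR/(P+R),
average precision and PR curves over probability thresholds, and two-sided
paired t-tests between arms.

The diffusion stage fits the mono-exponential model
`S(b) = S0·exp(−b·ADC)` voxelwise by log-linear least squares and
synthesizes the high-b-value image at b = 1400 s/mm².

There is no deep-learning framework dependency: the 3D CNN engine
(convolutions, backpropagation, Adam) is implemented in Rcpp/R inside the
package and validated by finite-difference gradient checks.

## Worked example

Generate a fusion-advantage phantom cohort (lesion evidence split across
channels behind cancelling confounder fields), train the three singleton
baselines and the three fusion families, and compare test DSC:

```r
library(fuseseg)

cfg <- experiment_config(
  n_train = 12, n_test = 4,
  arms = c("T2W", "ADC", "HIGHB", "EF", "IF", "LF"),
  phantom = list(fusion_advantage_mode = TRUE),
  seed = 11)
res <- run_experiment(cfg)
print(res)
```

```
<experiment_result>
    arm       input_data fusion mean_dsc sd_dsc    ap auc_pr
1   T2W         T2W only      -   0.1424 0.1523 0.132  0.127
2   ADC         ADC only      -   0.3335 0.1789 0.376  0.371
3 HIGHB       HIGHB only      -   0.0738 0.0562 0.348  0.334
4    EF mpMRI & clinical     EF   0.6516 0.3361 0.807  0.802
5    IF mpMRI & clinical     IF   0.6044 0.2814 0.577  0.570
6    LF mpMRI & clinical     LF   0.3604 0.1612 0.564  0.560
```

Reading the table: each single mpMRI channel alone supports only weak
lesion segmentation (mean test DSC 0.07–0.33) because each channel's
evidence is masked by a confounding field; every fusion family exceeds
every singleton because the channel combination cancels the confounders —
early fusion can do so voxel by voxel, intermediate fusion at the feature
level, and late fusion by averaging members whose errors are
anticorrelated.  `res$pairwise_p` holds the paired t-tests between arms and
`res$reports$EF$pr_curve` the PR curves.  (Numbers above are the output of
this exact call; they vary across master seeds.)

Lower-level pieces are exported directly, e.g.:

```r
spec <- phantom_spec(fusion_advantage_mode = FALSE, n_patients = 1, seed = 1)
p <- generate_patient(spec, 1)
fit <- fit_adc(p$dwi_series, p$b_values)           # voxelwise S0, ADC
hb <- synthesize_high_b(fit, b_target = 1400)      # synthetic high-b image
f_score(0.36, 0.13)                                # 0.1910204 -> 0.19
```

## Command line

A thin CLI over the same functions ships in `inst/cli/fuseseg.R` with
subcommands `generate`, `preprocess`, `train`, `evaluate`, `compare`,
`run-all` (exit codes: 0 ok, 2 config error, 3 data error, 4 stage
failure), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/fuseseg.R", package="fuseseg"))')" \
  generate --config phantom.json --out cohort/ --seed 1
```

where `phantom.json` holds `phantom_spec()` arguments (the config schema is
the function's argument list; same for `experiment_config()` and `run-all`).

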