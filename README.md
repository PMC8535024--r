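# voltexture

Volumetric GLCM texture analysis and lesion classification for
multiparametric prostate MRI.

## The problem

Distinguishing clinically significant prostate cancer (csPCa, Gleason
score ≥ 3+4) from indolent lesions and false-positive findings on mpMRI is
usually done with the radiologist-assigned PI-RADS score; the common rule
"csPCa iff PI-RADS ≥ 4" is reader-dependent and unspecific. Tumor
heterogeneity is a primary imaging feature of csPCa, and co-occurrence
statistics of the lesion's intensity field capture it quantitatively.
`voltexture` implements a texture-first classification pipeline for paired
T2-weighted / ADC volumetric lesion patches:

1. **Preprocessing** — per-patch min-max normalization to [0, 255] and
   quantization into 64 gray levels, `ℓ(v) = ⌊v·64/256⌋ + 1`.
2. **3D GLCM extraction** — for displacement `d = (di, dj, dk)`,

   ```
   GLCM_d(x, y) = Σ_{i,j,k} 1{ f(i,j,k) = x  ∧  f(i+di, j+dj, k+dk) = y }
   ```

   computed along the 13 canonical immediate-neighbor directions (the 26
   neighbors of a voxel modulo `d ~ −d`), per modality: a 26-channel stack
   of 64×64 matrices, normalized to probabilities so the input is
   patch-size invariant.
3. **Classifiers** — a compact CNN on the stack (conv 3×3 26→32 + BN +
   ReLU, pool 2×2, conv 3×3 32→64 + BN + ReLU, pool 2×2, FC 16384→256→2,
   softmax; weighted cross-entropy, Adam at 1e-5, 200 epochs, batch 10,
   validation-AUC checkpoint); a random-forest baseline on the 104
   directional Haralick features (contrast, correlation, homogeneity,
   energy × 13 directions × 2 modalities; 50 trees, Gini, pure leaves,
   bootstrap); and the PI-RADS ≥ 4 rule baseline.
4. **Evaluation** — Mann-Whitney AUC with 1000-resample percentile
   bootstrap CIs, Youden operating points, Wald CIs for
   sensitivity/specificity/PPV/NPV, paired DeLong and McNemar tests
   against the rule baseline, and clinical subgroup reports (zone,
   focality, PI-RADS score, index lesions by PSA stratum).

No clinical images ship with the package: a texture-phantom generator
(`generate_cohort()`) emulates a labeled ~400-patient cohort whose classes
differ in texture heterogeneity (Gaussian random fields with
class-dependent blur plus an ADC core drop for csPCa), with patient-level
60/10/30 splits, so the whole pipeline runs offline and reproducibly. The
methods vignette (`vignettes/glcm-texture-classification.Rmd`) documents
the model, its conventions, and what phantom results do and do not show.

## Worked example

```r
library(voltexture)

run <- run_pipeline(run_config(seed = 1))   # ~13 min on one core
run
#> <vt_run> 461 lesions; test AUCs:
#>   textured_cnn   0.998 [0.994, 1.000]
#>   textured_rf    1.000 [1.000, 1.000]
#>   pirads_cla     0.705 [0.630, 0.778]
```

Both texture models separate the phantom classes almost perfectly — the
separation is present by construction — while the synthetic PI-RADS rule
sits near the sensitivity/specificity trade-off its confusion table
encodes (0.89 / 0.52 here, AUC 0.705 as a two-level score). The evaluation
tibble (`run$eval`, or `tidy(run)`) carries the full per-subgroup report;
for example, in the peripheral zone (n = 102 test lesions) the CNN's
specificity is 0.974 [0.925, 1.000] versus the rule's 0.513
[0.356, 0.670], McNemar p = 7.6e-06:

```r
subset(run$eval, group == "zone_PZ" & model == "textured_cnn",
       c(auc, specificity, spec_lo, spec_hi, p_mcnemar_spec))
```

Every stage is exposed on its own: `generate_cohort()`, `split_cohort()`,
`normalize_0_255()` / `quantize()`, `canonical_directions()` /
`glcm_single()` / `glcm_stack()`, `haralick4()` / `feature_table()`,
`train_cnn()` / `train_rf()` / `pirads_cla()`, and the statistics
(`auc_mw()`, `bootstrap_auc_ci()`, `youden_point()`, `wald_ci()`,
`delong_test()`, `mcnemar_test()`, `evaluate_models()`). `autoplot()`
methods draw ROC curves, training logs, and GLCM channels; `tidy()` /
`glance()` methods summarize fitted objects. A thin command-line wrapper
(`exec/voltexture`) maps subcommands (`generate`, `extract`, `features`,
`train-cnn`, `train-rf`, `evaluate`, `run-all`) onto these functions, with
YAML configuration.

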