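# flairsir

Quantitative estimation of ischemic stroke lesion age from multimodal
MRI, built around the FLAIR **signal-intensity ratio (SIR)**.

## The problem

Roughly 15–30% of ischemic strokes are noticed on awakening, so the true
onset time — which gates intravenous thrombolysis at 4.5 hours — is
unknown. Imaging can substitute for the clock: diffusion restriction
(low ADC on DWI) appears within minutes, while FLAIR hyperintensity
develops over hours. The SIR quantifies that lag:

```
SIR = mean FLAIR signal over the DWI-defined lesion
      ------------------------------------------------
      mean FLAIR signal over the mirrored contralateral ROI
```

where the lesion is segmented automatically as brain voxels with
ADC < 600×10⁻⁶ mm²/s (ADC from the two-b-value decay
`S_b = S0·exp(−b·ADC)`), and the reference region is the lesion mask
reflected about the mid-sagittal plane. A patient with SIR above a
cutoff (default 1.115) is classified as beyond the 4.5 h window.

The package implements the full inference chain around the statistic,
for imaging scientists and biostatisticians who want a tested,
self-contained reference implementation:

* `make_phantom()` / `generate_cohort()` — seeded synthetic DWI/FLAIR
  phantoms with known ground truth, and patient-level cohorts emulating
  a 633-patient two-centre stroke study (onset-time laws, covariate
  prevalences, a censored linear SIR model in log lesion age and large
  vessel occlusion).
* `compute_adc()`, `segment_lesion()`, `compute_sir()`,
  `classify_window()` — the imaging pipeline (NIfTI in/out via RNifti).
* `build_two_by_two()`, `odds_ratio()`, `roc_curve()`,
  `delong_paired_test()`, `youden_cutoff()` — contingency diagnostics
  and ROC analysis with DeLong variance.
* `fit_logistic()` (in-package IRLS), `stepwise_select()`,
  `hierarchical_blocks()` (R²-change F tests), `risk_score()`.
* `run_mediation()` — counterfactual mediation (ACME/ADE/total with
  quasi-Bayesian or bootstrap CIs) of the SIR→onset-window pathway
  through large vessel occlusion.
* `run_study()` / `reproduce_printed()` — end-to-end orchestration and
  verification against embedded published counts. A thin CLI
  (`exec/sirpipe`) exposes `simulate`, `phantom`, `sir`, `analyze`,
  `reproduce`, `all`.

Fitted objects follow tidyverse conventions: `tidy()`, `glance()`,
`autoplot()` methods, tibbles in and out.

## Worked example

```r
library(flairsir)

# A noisy phantom with known truth: lesion/mirror ratio 1.25
ph <- make_phantom(phantom_spec(target_sir = 1.25, noise_sd = 10, seed = 42))
m  <- measure_sir(ph$b0, ph$b1000, ph$flair, ph$brain_mask)
m$sir_result
#> SIR = 1.2423 (lesion 249.8 / mirror_roi 201.1 over 257 voxels)
m$predicted_late
#> [1] TRUE
```

The measured SIR (1.2423) sits within noise of the generated truth
(1.25) and exceeds the 1.115 cutoff, so the lesion is classified as
older than 4.5 h. On a synthetic cohort, the mediation analysis asks
how much of the SIR–onset-window association flows through large vessel
occlusion:

```r
cohort <- generate_cohort(cohort_config(seed = 1))
run_mediation(cohort, n_sims = 1000, seed = 2)
#> Causal mediation (sir -> lvo -> late), quasi-bayesian, 1000 draws, contrast 1.07 vs 1.2
#> # A tibble: 4 × 4
#>   effect        estimate ci_low ci_high
#>   <chr>            <dbl>  <dbl>   <dbl>
#> 1 acme            0.0608 0.0198   0.104
#> 2 ade             0.232  0.163    0.299
#> 3 total           0.293  0.236    0.348
#> 4 prop_mediated   0.208  0.0646   0.383
```

Moving SIR from its 25th to its 75th percentile raises the probability
of a late onset window by 0.29; about a fifth of that effect is carried
by LVO (both ACME and ADE CIs exclude zero — partial mediation).

```r
v <- reproduce_printed()
attr(v, "all_match")
#> [1] TRUE
```

`reproduce_printed()` recomputes 66 values that are derivable from the
embedded integer counts of the reference study — group percentages,
chi-squared p-values, univariate odds ratios with Wald CIs (e.g.
hyperlipemia 5.453, LVO 4.019), and the full diagnostic rows of the
three binary onset-window predictors including DeLong AUC CIs — and
checks each at its printed precision.

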