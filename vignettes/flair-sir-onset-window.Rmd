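---
title: "Estimating the stroke onset window from the FLAIR signal-intensity ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the stroke onset window from the FLAIR signal-intensity ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flairsir)
```

## The problem

About one in five ischemic strokes is noticed on awakening, so the true
onset time — which gates intravenous thrombolysis at 4.5 h — is unknown.
Tissue state can stand in for the clock: cytotoxic edema restricts water
diffusion within minutes (visible on DWI, with low apparent diffusion
coefficient, ADC), while FLAIR hyperintensity develops over hours as
vasogenic edema accumulates. A lesion that is DWI-positive but still
FLAIR-negative ("DWI-FLAIR mismatch") is therefore probably young. The
visual mismatch rating is specific but insensitive and poorly
reproducible, which motivates a quantitative replacement: the FLAIR
**signal-intensity ratio (SIR)**,

$$\mathrm{SIR} = \frac{\overline{S}_{\mathrm{FLAIR}}(\mathrm{lesion})}
                     {\overline{S}_{\mathrm{FLAIR}}(\mathrm{mirror})},$$

the mean FLAIR signal inside the DWI-defined lesion divided by the mean
over the same region reflected into the contralateral hemisphere. SIR
rises with lesion age; a patient whose SIR exceeds a cutoff (1.115 by
default here) is classified as beyond the 4.5 h window.

This package implements the whole inference chain around that statistic:
lesion segmentation from two-b-value DWI, the SIR itself, 2x2
diagnostics and odds ratios, empirical ROC curves with DeLong variance
and paired AUC comparison, logistic and hierarchical block regression,
and counterfactual mediation of the SIR-onset relationship through
large vessel occlusion (LVO) — exercised entirely on synthetic phantoms,
synthetic cohorts, and an embedded table of published integer counts.

## The imaging statistic

`compute_adc()` inverts the mono-exponential diffusion decay
$S_b = S_0 e^{-b\,\mathrm{ADC}}$ from a $b=0$ and a $b=1000$ s/mm$^2$
volume; voxels with non-positive signal are marked invalid and excluded.
`segment_lesion()` takes brain voxels with ADC strictly below
$600\times10^{-6}$ mm$^2$/s — the conventional acute-core threshold —
and keeps 26-connected components of at least 5 voxels (the size filter
suppresses isolated noise voxels; the value is a package choice, as
ROI tools rarely document theirs). The contralateral reference is the
lesion mask reflected about the mid-sagittal grid plane and intersected
with the brain mask.

Two reference-region readings are plausible: the mirrored ROI itself, or
the mean over the whole contralateral hemisphere at the lesion's slices.
Both appear in the literature, sometimes in the same report. The
mirrored ROI is the default (`reference = "mirror_roi"`) because it
compares homologous tissue and is insensitive to hemisphere-scale
intensity structure; the alternative is available as
`reference = "hemisphere_slice_mean"`. Means, not medians, are used
within regions, matching the "average signal intensity" convention.
All thresholds are strict inequalities (`ADC < threshold`,
`SIR > cutoff`), so a value exactly at a boundary is classified
conservatively (not lesion; not late).

Coordinates: axis 1 of every volume is left-right; the mirror plane sits
between columns for even extents and on the centre column for odd ones,
making reflection an exact voxel permutation. Real-data midline
estimation and DWI-FLAIR registration are out of scope — volumes are
assumed co-registered and midline-aligned, as after standard axial
acquisition.

## The phantom model

`make_phantom()` builds a mirror-symmetric "brain" (an ellipse in the
axial plane extruded across slices) with a single spherical lesion in one
hemisphere, on a 48x48x12 grid at 4x4x6 mm spacing by default. DWI
signals follow the exponential law exactly (background ADC
$8\times10^{-4}$, lesion $4\times10^{-4}$ mm$^2$/s); the FLAIR lesion is
hyperintense by a known factor `target_sir`. With zero noise the
measured SIR equals the target to machine precision, which is the
package's imaging-exactness gate.

Noise is additive Gaussian, clamped at zero. Rician noise — the correct
magnitude-image model — is deliberately ignored: at the signal-to-noise
ratios exercised here the two are indistinguishable for ratio recovery,
and the simplification keeps the truth values exact. This is a
documented limitation, not an oversight. When the tests quote an SNR,
it is referenced to the diffusion-weighted ($b=1000$) background tissue
signal ($S_0 e^{-0.8} \approx 449$), the standard way DWI SNR is
reported; at SNR 20 under that definition, threshold segmentation
recovers the lesion with Dice $\ge 0.95$.

## The synthetic cohort

`generate_cohort()` draws patient tables whose marginal structure mimics
a two-centre acute stroke cohort of 358 early (onset-to-MRI $\le$ 4.5 h)
and 275 late (> 4.5 h) patients. Onset times are log-normal per group,
truncated to the group's side of the cutoff and capped at 24 h (the
inclusion criterion); the log-normal parameters are fitted so that the
*truncated* law matches the target quartiles (3.5 h with IQR 1.5-4, and
7.5 h with IQR 6-12) — naive median/IQR matching before truncation
would shift the early median to about 2.5 h. Binary covariates are drawn
independently at their per-group prevalences (hyperlipemia 9.2%/35.6%,
LVO 31.0%/64.4%, and so on). The SIR follows

$$\mathrm{SIR} = \beta_0 + \beta_1 \log(1+t) + \beta_2\,\mathrm{LVO} +
  \varepsilon,\qquad \varepsilon \sim N(0, \sigma^2),$$

censored below at 1: in this model a lesion cannot be systematically
darker than its mirror tissue. The frozen defaults
($\beta_0 = 0.984$, $\beta_1 = 0.065$ per log-hour, $\beta_2 = 0.075$,
$\sigma = 0.065$) were calibrated once, by grid search, against the
generator's stated targets: group SIR medians near 1.10 and 1.17, an
overall Spearman correlation of SIR with time around 0.5, a weaker
correlation within the LVO stratum, and mismatch-surrogate prevalences
within a few points of 57.3%/20.4%.

The DWI-FLAIR mismatch flag is a *thresholded surrogate* for the human
visual rating: mismatch is present when SIR < 1.115. A higher surrogate
threshold (e.g. 1.15) looks natural but is incompatible with the
calibration targets: at the calibrated SIR spread it would label about
75%/38% of the two groups as mismatch rather than ~57%/20%. The
threshold is a config parameter, not a claim about how radiologists
read images. The PWI/DWI mismatch ratio and DWI lesion volume are
sampled from quartile-matched log-normals but carry **no** effect on the
outcome, so they act as calibrated null covariates — the hierarchical
regression is expected to attribute essentially zero R-squared change
to them.

Two behaviours of this generator are worth knowing before interpreting
test output. First, the pooled SIR-time correlation exceeds both
within-stratum correlations, because the LVO shift is aligned with the
late group; this reproduces the qualitative "weaker within LVO" pattern,
but the stratum-level ordering is stochastic at n = 633 (the sampling
error of a rank correlation at n ~ 300 is about 0.06), so tests check it
on seed averages. Second, the mediator structure is not monotone in
$\beta_2$ alone: a very large LVO-on-SIR shift makes LVO *explain away*
SIR in the outcome model and flips the mediated path negative. The
mediator-to-outcome path is governed by the LVO prevalence contrast
between groups, and the mediation-recovery test varies that contrast.

What the generator does **not** emulate: correlated risk factors (all
covariates are independent within group), measurement error in the
onset time, site effects, lesion-size dependence of the SIR, or any
image-level realism beyond the phantom. A test passing on this cohort
shows the *statistical machinery* is correct under the stated model; it
is not evidence about real patients.

## Statistical conventions

* **2x2 orientation.** The positive outcome is always the late window
  (> 4.5 h): `a` = predictor-positive late patients. Absence of
  DWI-FLAIR mismatch is the late-positive reading of the mismatch
  rating. For a binary predictor the ROC area equals
  (sensitivity + specificity)/2, and the conventional cutoff 0.5 is
  reported.
* **Odds ratios** are Wald: $\exp(\log\mathrm{OR} \pm z_{0.975}
  \sqrt{1/a+1/b+1/c+1/d})$, with an optional Haldane +0.5 correction for
  zero cells. Group comparisons use Pearson chi-squared without
  continuity correction (Yates available) and the Mann-Whitney U with
  normal approximation and tie correction.
* **ROC curves** are empirical, ties counting one half, so the AUC is
  identically the tie-corrected Mann-Whitney statistic $U/(n_1 n_0)$.
  The AUC variance and the paired-curve covariance use the DeLong
  structural components ($V_{10}$, $V_{01}$); the paired test statistic
  is $z = (A_1 - A_2)/\sqrt{v_1 + v_2 - 2c}$. Degenerate variance
  (a curve against itself) returns $z = 0$, $p = 1$ rather than NaN.
* **Operating points** maximise Youden's J over thresholds placed at
  midpoints between adjacent unique scores (ties broken toward the lower
  threshold), which yields 0.5 for binary predictors and midpoint-style
  cutoffs such as 1.115 for the SIR.
* **Logistic regression** is fitted by iteratively reweighted least
  squares written in-package, with step-halving so the log-likelihood is
  non-decreasing (a tested invariant), Wald standard errors from the
  inverse observed information, and an explicit separation flag instead
  of silently huge coefficients. `glm()` serves as an independent
  cross-check in the test suite, never as the implementation. Stepwise
  selection is backward elimination at Wald p $\ge$ 0.05 after a
  univariate entry screen at p < 0.05; on the default cohort it retains
  hyperlipemia, LVO and the SIR, though at other seeds an additional
  weak covariate can survive — expected behaviour of stepwise selection
  at $\alpha = 0.05$, not a defect.
* **SIR scaling in regression.** Per-unit odds ratios for a predictor
  whose whole range is ~0.4 are astronomically scaled and numerically
  fragile; the pipeline therefore enters SIR per 0.01 units
  (`sir_rescaled = 100 * sir`), and odds ratios for SIR are to be read
  per 0.01 SIR.
* **Hierarchical blocks.** The stratified-adjustment table reports
  B ± SE, R-squared, adjusted R-squared and F statistics — ordinary
  least-squares quantities — so the default family is OLS on the 0/1
  outcome (a linear probability model), with the F-change test
  $F = \frac{(R^2_{full}-R^2_{red})/q}{(1-R^2_{full})/(n-k-1)}$.
  A deviance-based logistic variant (McFadden pseudo-R-squared,
  likelihood-ratio chi-squared change) is available via
  `family = "logistic"`. Duplicated or collinear columns are dropped
  with a warning and contribute zero change by construction.

## Mediation

`run_mediation()` re-implements the counterfactual simulation estimator
for a binary mediator and binary outcome (logistic component models;
OLS for continuous variables). Parameters are drawn from their
asymptotic normal distribution (quasi-Bayesian, 1000 draws by default;
subject-resampling bootstrap as the alternative); for each draw the
counterfactual mediator distribution is imputed under the two treatment
values and potential-outcome differences are averaged over subjects.
For a binary mediator the averaging over mediator states is analytic,
so no Monte-Carlo noise enters beyond the parameter draws. Effects are
averaged over the two treatment arms, which makes
$\text{total} = \text{ACME} + \text{ADE}$ an exact identity within
every draw (tested to 1e-10). The treatment contrast for the continuous
SIR is the cohort's 25th-to-75th percentile span — a deliberate choice,
since a full-unit SIR change is physiologically meaningless. Hyperlipemia
enters both component models as a control covariate. The proportion
mediated ACME/total is summarised by its median across draws and is
reported only when the total-effect CI excludes zero, since the ratio is
unstable otherwise. Sequential-ignorability sensitivity analysis and
multiple mediators are out of scope.

## The verification surface

Individual-level data behind the reference study are not publicly
deposited, so dataset-level results (e.g. the published SIR-model AUC of
0.773 or the multiparameter 0.869) cannot be recomputed exactly and are
covered only as qualitative/stochastic properties on the synthetic
cohort. What *is* exactly recomputable is everything derivable from the
published integer counts, embedded in `table1_counts()`:
`reproduce_printed()` recomputes 66 such values — group percentages,
chi-squared p-values, univariate odds ratios with Wald CIs, and the
complete diagnostic rows (including DeLong AUC CIs) of the three binary
predictors — and checks each at its printed precision (half-up, with a
one-unit allowance in the last printed digit, which also covers a
0.669/0.670 rounding inconsistency in the reference accuracy of the LVO
row). Three reference odds-ratio rows (hypertension, diabetes, atrial
fibrillation) are printed in the reciprocal orientation relative to
their own counts; the verifier reports them with an explanatory note and
excludes them from the pass gate.

Problem sizes used by the test suite are package choices balancing
precision against brevity: 1000 random inputs for the AUC/U identity,
500 null simulations at n = 100 for the DeLong size check, 50-100 seeds
for calibration and mediation-coverage bands, and 200 seeds for Wald CI
coverage. `scripts/acceptance.R` re-runs the main computations from
scratch at a user-supplied seed and writes every headline quantity as
JSON.

## Known limitations

Gaussian rather than Rician image noise; a geometric phantom rather than
anatomy; a single pooled lesion (no per-lesion reporting); no
registration, midline estimation, or CSF exclusion in the mirror region;
independent covariates in the generator; stepwise selection inherits the
usual instability of p-value-driven procedures; the linear probability
model can produce fitted values outside [0, 1] (the logistic family is
provided for that reason); and the mediation estimator assumes
sequential ignorability, which synthetic data satisfy by construction
but real data need not.
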