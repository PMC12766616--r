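---
title: "Strain heterogeneity biomarkers: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain heterogeneity biomarkers: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainhet)
```

## The biomarker and why it works

Peak systolic strain is measured per segment of the AHA 16-segment left
ventricular model (6 basal, 6 mid, 4 apical; no apical cap) in three
directions. Raw longitudinal and circumferential strain are negative
(shortening), radial strain is positive (thickening); all derived
biomarkers work on absolute values. Global strain (GLS/GCS/GRS) is the
mean of the 16 absolute segmental values; the heterogeneity biomarker is
their coefficient of variation,

$$\mathrm{CoV} = \frac{\mathrm{SD}(|Y_1|,\dots,|Y_{16}|)}
                      {\mathrm{Mean}(|Y_1|,\dots,|Y_{16}|)},$$

one per direction (CoV~LS~, CoV~CS~, CoV~RS~). The CoV is scale-free: a
*uniform* change of contractility moves global strain but not the CoV,
while a *regional* lesion (a few contiguous hypokinetic segments) moves
the CoV sharply and the global mean only mildly. `strain_cov()` is tested
against this discriminating property directly.

**SD denominator.** The defining ratio does not pin down the SD divisor.
We default to the sample SD (n − 1), the standard estimator for a 16-item
sample, and expose `denominator = "population"`; the choice is recorded in
the QC report options. At n = 16 the difference is a constant factor
(√(15/16) ≈ 0.968) and does not affect any rank-based or model-based
downstream result.

## Quality control cascade

`apply_qc()` runs, in order: (1) participants with no strain rows are
counted out; (2) cells with physiologically impossible sign (including
exact zero and non-finite values) are invalidated; (3) per direction,
cohort fences `Q1 − k·IQR` / `Q3 + k·IQR` (default `k = 3`, quartiles by
linear interpolation — the most common convention; alternative quantile
estimators move 3×IQR fences negligibly at cohort scale) are applied to
the absolute segmental values, with values *strictly* beyond a fence
invalidated and values exactly on a fence retained (conservative
retention); (4) biomarkers are computed from surviving cells, with a CoV
from ≤ 6 valid segments set missing while global strain is kept down to a
single valid segment — the exclusion rule names the CoV, whose
sampling error explodes at small segment counts, not the mean;
(5) the same fences are applied to the six derived biomarkers
(`fence_scope` selects segmental, biomarker-level, or both — both by
default, since "raw strain output" censoring plausibly covers either
reading).

QC never deletes rows: `valid` and `flag` are recomputed from the raw
values, which makes the cascade idempotent by construction (re-running it
on its own output is a no-op, verified in the tests).

`assess_missing_segment_impact()` reproduces the evidence behind the
minimum-segment rule: for a complete 16-segment set it recomputes the CoV
over all (or sampled) size-k subsets and reports bias and dispersion
against the full-set CoV, exhaustively enumerated when `choose(16, k)` is
small.

## The synthetic cohort generator

`simulate_cohort()` emulates the data structure of a large population
imaging study. Its defaults are the package's fixed study conditions:

- **Strain model.** Per direction, segment value = sign × (healthy mean +
  participant effect + segment noise), magnitudes clamped at 0.1% so raw
  signs stay valid. Healthy means are anchored to published
  healthy-reference medians (18.4 / 18.9 / 31.4% absolute). The paper
  trail for healthy *between-segment* variance does not exist in the
  source material, so segment noise SDs (6.1 / 3.0 / 8.8%) were
  calibrated once so that healthy CoV medians land near 0.33 / 0.16 /
  0.28 — a documented modeling choice, not a literature fact.
  Between-participant SDs (1.4 / 2.1 / 5.5%) similarly reproduce the
  observed global-strain interquartile ranges after accounting for the
  segment-noise contribution to the 16-segment mean.
- **Circumferential–radial coupling.** Circumferential shortening and
  radial thickening are two projections of the same mid-wall
  deformation, so their segment noise and participant effects share a
  latent factor with correlation 0.97 (`cs_rs_noise_cor`), and lesions
  always attenuate both directions through one shared mask (longitudinal
  coupling is probabilistic, `lesion_ls_coupling = 0.5`). This reproduces
  the very strong CoV~CS~–CoV~RS~ correlation reported for real cohorts
  (ρ ≈ 0.9) as an emulation property.
- **Lesions.** A lesion multiplies the magnitude of `lesion_n_segments`
  *contiguous* segments by `lesion_attenuation`. Contiguity is defined on
  ring adjacency within each level plus radial level-to-level alignment
  (basal i ↔ mid i+6; apical 13–16 aligned to the mid segments of the
  same wall), mimicking coronary-territory lesions.
- **Outcomes.** Five endpoints (composite CV, MI, HF, arrhythmia,
  death) get Weibull-baseline proportional-hazards times via inverse
  transform, with per-endpoint log hazard ratios applied to the measured
  (pre-artifact) biomarkers and covariates — so recovery experiments can
  target an exact HR per SD. Death censors the non-fatal endpoints
  (cause-specific convention; no competing-risks machinery, matching the
  modeling scope). Prevalent-disease flags are drawn independently and
  excluded from the corresponding incidence models.
- **Censoring.** Administrative cutoff at 6.5 years plus, with
  probability 0.64, an independent Uniform(0, 6.5) dropout time. This
  two-parameter model reproduces the skewed follow-up pattern of a staged
  imaging sub-study (median ≈ 5.1, Q1 ≈ 2.4, Q3 = 6.5 years) without
  modeling accrual explicitly. Baseline Weibull scales are calibrated so
  default event fractions land near composite 2.8%, MI 0.9%, HF 0.7%,
  arrhythmia 1.8%, death 1.3% over that follow-up.
- **Artifacts.** `inject_artifacts()` empties whole participants, drops
  segments, flips signs, and substitutes extreme values placed strictly
  beyond the clean cohort's Q3 + 3·IQR fence (at 4–7 IQR, correct sign,
  so only the fence rule can catch them). Every corrupted cell is
  recorded in a ledger, making QC recall and precision measurable.

**What the generator does not emulate**: correlated comorbidity
structure (risk factors are drawn independently, so the healthy-reference
fraction is lower than in a real cohort where risk factors cluster),
informative censoring, measurement drift between scanners, ICD-coded
outcome ascertainment, and segment-level spatial noise correlation within
a direction. Passing tests therefore demonstrate the *statistical
machinery* — estimator correctness, calibration, power under known
signal — not clinical validity on real data.

## Modeling stack

Models are nested per focal biomarker and endpoint: tier 1 = z-scored
focal marker only; tier 2 adds age, sex, ethnicity, smoking, BMI,
dyslipidemia, hypertension, diabetes; tier 3 adds LVMi, LVEDVi, LVEF and
the reciprocal strain marker (each CoV paired with its global
counterpart and vice versa). Strain markers are z-scored over the
analyzed sample; other covariates enter on their natural scale. Fitting
is the Cox partial likelihood with Efron tie handling (Breslow by flag),
convergence at relative log-likelihood change < 1e−9 within 100
iterations; complete cases per model, with participants excluded when the
modeled endpoint was prevalent at baseline (an `exclude = "any_cvd"`
global option exists, since the exclusion scope is a judgment call).

Comparison metrics, all implemented in-package and pinned to brute-force
oracles in the tests:

- **Uno's C-index**: IPCW pair sum truncated at τ, weights
  1/G(T⁻)² from the left-continuous Kaplan-Meier estimate of the
  censoring distribution, risk ties counting ½. τ defaults to the 95th
  percentile of observed follow-up (no published value exists to adopt)
  and is carried in the output. With no censoring it equals Harrell's C
  exactly.
- **ΔC bootstrap**: B = 200 participant-level resamples by default,
  both models refit per resample, p from an unpaired t-test between the
  two bootstrap C distributions — implemented as stated even though the
  unpaired construction on overlapping resamples is anticonservative; a
  paired percentile-bootstrap p is always reported alongside it.
- **Continuous NRI(>0)**: IPCW-weighted event/non-event re-ranking
  proportions at the horizon, in percent (+200 saturation), with a
  percentile bootstrap interval (the interval method is an assumption,
  flagged as such).
- **Brier score at 5 years**: Graf-style IPCW mean squared error between
  predicted risk (baseline cumulative hazard × exp(lp)) and horizon
  status.
- **LRT / ΔAIC** on identical rows; "improvement" reported when
  ΔAIC < −2 and LRT p < 0.05.
- **Multiplicity**: Bonferroni with m = 15 (3 principal CoV-vs-global
  comparisons × 5 endpoints), α = 0.05/15 ≈ 0.0033.

Diagnostics: scaled Schoenfeld residual tests per covariate and VIFs
from auxiliary regressions on the design matrix (pass at VIF < 5);
both are attached, since graphical-only Schoenfeld assessment cannot be
automated.

## Splines and Kaplan-Meier

The non-linearity test compares tier-3 models with the focal biomarker
entered linearly vs through a restricted cubic spline (truncated-power
basis with linearity constraints beyond the boundary knots, normalized by
the squared knot span; 4 knots → 3 columns → a 2-df LRT). "4 knots at
quartiles" is internally ambiguous — quartiles give 3 interior points —
so the default places knots at the 5th/25th/75th/95th percentiles and a
`"quartile"` rule (5th percentile anchor + Q1/Q2/Q3) is provided; the
rule used is carried in the output.

KM panels use the product-limit estimator per within-stratum tertile
(ties at a tertile cut go to the lower group), stratified by reduced
(< 50%) vs preserved LVEF; tertiles are computed within the stratum
because the stratified display is the unit of interpretation (a
`"cohort"` scope is available). Cumulative hazard is displayed as
−log S(t) for internal consistency with the product-limit estimator.
The trend test is the 1-df score test with equally spaced ordered
scores, hypergeometric variance; it reduces exactly to the two-sample
logrank test for two groups and is invariant to affine score recoding.

## Numerical and testing choices

Degenerate inputs are handled explicitly: constant collections give
zero-width fences and reference ranges (warned), zero-spread inputs to
`standardize()` and `tertile_split()` are errors, duplicate spline knots
are an error advising fewer knots, subgroups with no events are reported
as not-estimable rows rather than failures, and `simulate_outcomes()`
floors times at 1e−8 to keep them strictly positive.

The test suite's simulation sizes are chosen to give each check adequate
Monte-Carlo resolution at desk scale: 200 replicates of n = 20,000 for
hazard-ratio recovery (the mean fitted HR then has standard error
≈ 0.006), 1000 replicates of n = 2,000 for the null-calibration rates
(binomial SE ≈ 0.7 percentage points), 15 replicates of n = 10,000 for
the model-comparison power check (where the per-replicate power is
essentially 1), and 100 replicates of n = 4,000 for the LVEF-stratified
KM pattern. Oracle-equivalence checks run on ≥ 100 random instances of
n ≤ 100 per estimator against naive loop implementations kept in the
test helpers.

## Known limitations

- The pipeline starts from segmental strain tables; image analysis and
  feature tracking are upstream and out of scope, as are ICD code
  parsing, competing-risks models, multiple imputation and time-varying
  covariates.
- The CoV's ~% display convention follows the field's labeling even
  though SD/mean is dimensionless.
- The unpaired bootstrap t-test for ΔC is reproduced as specified; for
  new analyses the paired percentile p-value reported next to it is the
  safer quantity.
- Generator realism limits are listed above; in particular, independent
  risk-factor draws shrink the healthy-reference fraction relative to
  real cohorts, which slightly widens simulated reference ranges'
  sampling error at a given cohort size.
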