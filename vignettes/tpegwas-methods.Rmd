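---
title: "Methods: from exercise ECG to genetic architecture, at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from exercise ECG to genetic architecture, at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpegwas)
```

`tpegwas` couples a single-lead exercise-ECG measurement pipeline to a
desk-scale genetic-analysis scaffold. This vignette records the models, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic-data tests do and do not demonstrate about real data.

## The measurement model

An exercise stress test is modelled as three phases: 15 s rest, 6 min of
graded exercise, 1 min of recovery (`exercise_protocol()`, durations in
seconds). The RR interval ramps linearly from `rr_rest` (default 1000 ms) to
`rr_peak` (600 ms) during exercise and relaxes exponentially towards
`rr_recovery` (900 ms) with a 10 s time constant. Published descriptions of
such protocols give only a schematic RR profile; the linear ramp and
exponential relaxation are this package's choices. The workload-to-heart-rate
mapping of a real bicycle test is not modelled: any profile that is constant
at rest, monotone during exercise and relaxing in recovery would serve the
same testing purpose, and 10 s is a physiologically sensible heart-rate
recovery constant (the analysis window sits 42.5–57.5 s into recovery, >4
time constants in, so the residual RR transient there is under 2 % of the
peak-to-recovery change).

Each beat is a stylised QRS-T complex: a triphasic QRS built from three
narrow Gaussians (Q at −20 ms, R at 0, S at +22 ms relative to the R peak)
and a Gaussian T-wave of amplitude `t_amplitude` (default 0.3 mV) and width
`t_sigma` centred `t_center_offset` (default 300 ms) after QRS onset. The
Gaussian T-wave is the load-bearing choice: its tangent-method T-end has the
closed form μ + 2σ, so the ground-truth Tpe is exactly 2σ and every
delineation estimate has an analytic oracle. Phase-specific Tpe is produced
by scaling σ per beat along the same profile shape as RR; the generator logs
per-beat truth (time, RR, Tpe) alongside the signal, and the processing
pipeline never reads it.

Gaussian bumps are evaluated on a ±8σ support; the truncation error
(~1e−14 of the amplitude) is far below every tolerance used in testing, so
nominally identical beats are identical to numerical precision regardless of
where the support boundary falls on the sample grid.

## Pre-processing and averaging

Filtering is a 4th-order Butterworth low-pass at 50 Hz plus a 2nd-order
high-pass at 0.5 Hz, both run forward-backward (`signal::filtfilt`) so
fiducial timings are not phase-shifted. Only the cutoffs are dictated by the
measurement problem (mains/muscle noise above, baseline wander below); the
orders are this package's choice, kept low because zero-phase application
squares the magnitude response. Sampling below 100 Hz, or a low-pass cutoff
at/above Nyquist, is rejected.

QRS detection is energy-based: band-pass 5–25 Hz, squaring, a 120 ms
moving-average envelope, a global threshold at 25 % of the envelope's 99th
percentile, a 250 ms refractory period, and refinement of each detection to
the local maximum of |amplitude| within ±50 ms. On clean synthetic records
it detects every beat with sub-sample RR accuracy; the test suite requires
≥99 % sensitivity and positive predictive value up to a noise SD of 5 % of
the R amplitude. A flat or empty signal returns zero detections with a QC
flag rather than an error. Any detector meeting the sensitivity property
would be acceptable; this one was chosen for having no tunable state beyond
the two thresholds above.

The three analysis windows are 15 s spans: the first 15 s of rest, the last
15 s of exercise ("peak"), and a 15 s window centred 50 s after the end of
exercise ("recovery"). Published descriptions fix the window length and the
50 s recovery anchor but not the edges; anchoring "peak" to the end of the
exercise phase and centring the recovery window are this package's
conventions. Beats are aligned on the R fiducial and averaged on a fixed
−150 ms to +480 ms span. Beats correlating below 0.9 with the ensemble
template are excluded (an ectopy/artifact guard; the threshold is a
documented substitute for unavailable per-beat QC rules of real pipelines).
Fewer than three usable beats is a QC failure carried through as a flagged
record, never an exception.

## Delineation

On the averaged beat, QRS onset and offset are the first sustained
(4-sample) returns of |x − baseline| below 3 % of the R amplitude, scanning
out from the R peak; the isoelectric baseline is the median of the 40 ms
preceding QRS onset. The T apex is the maximum absolute deviation from
baseline in a window from 40 ms after QRS offset to 20 ms before the beat
end, refined by 3-point parabolic interpolation; polarity is free, so
inverted T-waves delineate identically. T-end is the tangent method: the
steepest post-peak slope (central differences, searched up to 250 ms after
the apex) extrapolated to the baseline crossing. With biphasic T-waves the
larger-|amplitude| lobe defines the apex — a documented limitation, not a
feature.

Whether the original bespoke delineators used tangent, threshold or area
methods is not knowable from published text; the tangent method is the
field-standard choice and, critically, has the Gaussian closed form that
makes ground-truth testing exact. All fiducials live on the beat's own
timebase, which makes delineation exactly time-shift invariant and
amplitude-scale invariant (both are property-tested). On noise-free Gaussian
templates the Tpe error is below one sample period (2 ms at 500 Hz) across
the physiological sweep 40–120 ms.

## Traits

Per individual: resting Tpe, and the responses
`(Tpe_rest − Tpe_peak)/ΔRR_ex` and `(Tpe_peak − Tpe_rec)/ΔRR_rec`. Both RR
deltas are stored as positive magnitudes (rest→peak and peak→recovery RR
change); the responses themselves can be negative and are never clipped. A
signed-ΔRR convention would only flip the sign of both responses uniformly;
the magnitude convention is the default because the deltas are displayed as
magnitudes in the standard presentation of this protocol. Records with
non-positive deltas, or with Tpe outside [20, 200] ms or RR outside
[300, 2000] ms (configurable plausibility bounds standing in for unavailable
cohort-specific QC), are flagged, not dropped silently; relaxing the bounds
never removes a previously passing record.

Pooling of two resting-Tpe cohorts concatenates records with disjoint ids
(overlap must be resolved upstream; a shared id is an error naming the
offender) and keeps the cohort tag without adding a cohort covariate —
downstream models adjust for genotyping array, not cohort, matching the
covariate sets below.

The inverse-normal transformation is rank-based with the Blom offset:
`qnorm((rank − 3/8)/(n + 1/4))`, average ranks for ties. The offset choice
is conventional rather than dictated; any standard offset preserves ranks
and near-unit variance, which are the properties the tests pin down.

## Association and variance components

The per-variant model is ordinary least squares of the (typically
inverse-normalized) trait on allele dosage plus trait-specific covariates —
sex, age, BMI, smoking, resting RR and array indicator for resting Tpe;
diabetic status and the phase-matched RR and ΔRR for the response traits —
with a two-sided Wald p from the t distribution. Large-cohort practice uses
linear mixed models to absorb relatedness and stratification; the simulated
cohorts here are unrelated and unstructured, where OLS estimates the same
additive effect, so the mixed-model machinery (the scalability core of
real-data pipelines) is deliberately not reproduced. The MAF floor defaults
to 1 %; monomorphic variants are skipped with a message; collinear
covariates are an error.

Conditional analysis is joint regression with the lead variant's dosage as
an extra covariate — with individual-level data available, the
summary-statistic approximations used at biobank scale are unnecessary. A
candidate whose dosage is numerically collinear with the lead (residual
norm² below 1e−8 of its original) is dropped and flagged rather than
assigned a meaningless p.

Heritability is Haseman–Elston regression: with standardized trait y and
GRM `A = ZZ'/m` from standardized dosages,
`h² = Σ_{i≠j} A_ij y_i y_j / Σ_{i≠j} A_ij²`, with a leave-one-individual-out
jackknife SE computed in closed form from row sums (O(n²) after the GRM).
The bivariate version regresses cross-trait products for the genetic
covariance and reports `r_g = cov_g/√(v_a v_b)`; non-positive heritability
estimates make r_g undefined and are flagged. HE estimates the same
estimand as the REML variance-components methods used at scale, is exact to
implement, and is fast at n of a few thousand; its larger sampling variance
is priced into all recovery tests, which assert agreement within two
jackknife SEs.

The percent variance explained follows the two-model recipe: residualize
the trait on its covariates, then subtract the adjusted R² of a
PCs-only model (top 10 genotype principal components) from that of a
variants-plus-PCs model. Duplicated or collinear variant columns are dropped
with a message, leaving the estimate unchanged.

## Multi-stage inference

Candidates are variants with discovery p < 1e−6. Locus definition is
greedy: the smallest-p unassigned candidate leads a locus and absorbs every
unassigned candidate on its chromosome within 500 kb (a member at exactly
500,000 bp is absorbed — "more than 500 kb away" founds a new locus; the
boundary is exercised in tests). The output partitions the candidate set and
every lead has the locus-minimal p. Replication requires
`p ≤ 0.05/m` over the m candidates taken forward *and* direction
concordance; the threshold is reported at two significant figures (0.05/21 →
2.4e−3, 0.05/7 → 7.1e−3) but applied unrounded. Full-dataset discovery adds
loci with combined p ≤ 5e−8 that did not already replicate. A secondary
signal at a locus requires its unconditioned p below 1e−6 and less than a
1.5-fold difference on the −log10 scale both between lead and secondary p
and between secondary and conditional p. Sex-stratified scans drop sex from
the covariates and flag a variant sex-specific when it is genome-wide
significant in one sex but not in the combined scan. `tally()` assembles
the headline counts and the heritability share `round(100·PVE/h²)`.

The package ships the published 28-row lead-variant summary-statistics
table for resting Tpe as a plain-text fixture (`lead_snv_table()`); feeding
its printed columns through the decision rules reproduces the published
15-replicated / 13-additional classification exactly, which is the strongest
available end-to-end check of the decision logic.

## Genetic risk score

Scores are weighted dosage sums with weights taken verbatim from trait
summary statistics and variants chosen by a p-value cutoff. The cutoff scan
fits `glm(outcome ~ standardized score, binomial)` per cutoff on a
log-spaced grid from 5e−8 to 1 (15 points by default) in a training split
and keeps the cutoff with the smallest association p — the standard
criterion of threshold-scanning PRS tools. Validation refits in a held-out
split (stratified on the outcome so prevalences match by construction;
training/validation overlap is an error) and reports the odds ratio per
score SD with a Wald p. LD clumping is omitted because the simulated
variants are in linkage equilibrium; with correlated variants the scan would
over-count signal, so a distance-based clump should precede it — a known
limitation rather than a hidden assumption. The two-step design's purpose —
optimizing in training does not inflate validation type-I error — is
asserted by simulation in the test suite.

## Synthetic cohorts and outcomes

Genotypes are Hardy–Weinberg hard calls, `Binomial(2, MAF)` with MAF uniform
on [0.05, 0.5] by default, independent across variants (no LD, no
relatedness, no stratification — all deliberately out of scope). Traits are
`y = Zb + e` on standardized dosages with the genetic component rescaled to
an *exact* sample variance h² and noise to 1 − h², so the realized
heritability of each generated cohort equals its target and recovery tests
measure estimator error, not generator drift. For trait pairs the second
effect vector is constructed with exact correlation r_g to the first.
Binary outcomes are logistic in the weighted dosage sum with the intercept
solved numerically for the target prevalence (0.6 % in the rare-outcome
setting the risk-score design mirrors).

## Problem sizes and determinism

Every stochastic generator takes an explicit seed and restores the caller's
RNG state; given a seed, all outputs are reproducible bit-for-bit. The
standard verification sizes, chosen to give each estimator clear signal
while keeping a full run in minutes on one CPU: heritability and genetic
correlation at n = 4,000 individuals × 2,000 variants (HE jackknife SE
≈ 0.02–0.03 on h², ≈ 0.15–0.20 on r_g at h² = 0.10); ECG-pipeline median
recovery over 200 full 435 s recordings at 500 Hz with zero noise; null
association calibration at 10,000 variants; risk-score null calibration over
120 train/validate replicates.

## What passing tests do and do not show

The generators emulate the statistical structure the methods assume —
Gaussian T-waves with known fiducials, linkage-equilibrium genotypes,
additive architecture, unrelated individuals. Passing tests therefore show
the implementation is correct under its assumptions, with calibrated error
control and unbiased recovery of generating parameters. They do not show
robustness to real ECG morphology (notched, biphasic or low-amplitude
T-waves, U-waves, motion artifact), to LD (locus definition by pure distance
and unclumped risk scores both degrade), to relatedness or stratification
(where OLS and HE would need mixed-model replacements), or to genotyping
error and imputation uncertainty, all of which are explicit non-goals.
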