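---
title: "Methods: FDG-stratified progression-pathway analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FDG-stratified progression-pathway analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdgpathways)
```

## The scientific problem

Cognitively normal older adults do not decline along a single trajectory.
Some remain stable for a decade; some progress to mild cognitive impairment
(MCI) and stop there; some pass through MCI to Alzheimer's dementia; and a
minority converts directly from normal cognition to dementia with no
documented MCI stage. `fdgpathways` operationalizes an analysis in which
baseline brain glucose metabolism — an FDG-PET MetaROI composite expressed
as a cohort z-score — is treated as a determinant of *which* pathway a
person follows, not merely of whether decline occurs.

The pipeline stages are: eligibility filtering, deterministic pathway
classification with confirmation smoothing, metabolic and cognitive
indices, discrete-time Markov transition modeling, person-time velocity
analysis, competing-risks estimation (Aalen-Johansen and Fine-Gray),
multinomial pathway prediction, and Youden-threshold discovery, with
bootstrap and Monte-Carlo utilities and a single orchestrator
(`run_pipeline()`).

## Pathway classification and confirmation

Subjects must be CN at a day-0 baseline visit, have a baseline FDG value,
and be followed at least 180 days. A worsened diagnosis at visit $i$ is
**confirmed** iff some later visit at least `min_confirm_days` (default
180) after it shows the same or a worse diagnosis; this suppresses
transient diagnostic fluctuation. Design choices that the data cannot
decide, made once and exposed as flags:

* **Terminal worsenings are accepted.** A worsening at the final visit has
  no lookahead; rejecting it would delete every terminal conversion, so it
  counts as confirmed (`accept_terminal = FALSE` flips this).
* **Confirmed states ratchet.** Reversions after confirmation never
  un-confirm; dementia is absorbing throughout.
* **"Documented MCI" means confirmed MCI.** A lone unconfirmed MCI visit
  before dementia still classifies as direct conversion, consistent with
  treating unconfirmed diagnoses as noise.
* **Event time** is the day of the first visit carrying the
  later-confirmed diagnosis — the first documented change — not the day of
  the confirming visit.

Labels are exhaustive and mutually exclusive: STABLE, MCI_ONLY, MCI_TO_AD,
DIRECT_AD. With `min_confirm_days = 0` every observed worsening confirms,
which the tests use as a degenerate-parameter oracle.

## Metabolic indices

FDG z-scores use the cohort mean and sample SD (n−1; switchable).
Tertiles (LOW/MID/HIGH) cut at empirical 1/3 and 2/3 quantiles; the fixed
clinical categories cut at ±0.5 with the interior interval closed, so
boundary values fall in the intermediate band. Cognitive reserve is
MMSE − ADAS/3. The vulnerability index,
$\max(0, 1 - z)\cdot\max(0, 30 - \text{reserve})/4$, is a package-defined
interaction score: the source analysis reports such an index without a
formula, so only its *ordering* across pathways is meaningful and only
ordering is asserted in tests. Amyloid positivity comes from a
two-component Gaussian mixture fit by EM with deterministic median-split
initialization (tolerance $10^{-8}$ on the log-likelihood, cap 2000
iterations — collapsing components approach the plateau slowly), calling
positive at posterior ≥ 0.5 for the higher-mean component; component
relabeling cannot change calls. The atrophy index is the first principal
component of standardized hippocampal volume, brain volume and their
ratio, sign-oriented so higher = worse (negative hippocampal loading).

## Markov transitions and sojourn times

Annual-cycle discrete time was chosen over continuous-time intensities
because the quantities of interest are *annual* transition probabilities;
the estimand then matches the estimator exactly. Each subject's confirmed
state is sampled at anniversaries (last confirmed state at or before each
anniversary day, LOCF), contributing cycles only up to the final visit
anniversary. Per-stratum maximum likelihood is transition counting:
$\hat p_{ij} = n_{ij}/\sum_j n_{ij}$. Rows are exactly stochastic by
construction and the dementia row is fixed at (0, 0, 1). Expected sojourn
time in a state with self-transition probability $p$ is the geometric mean
duration $1/(1-p)$, at least one cycle. Stratum contrasts are reported as
percentage-point differences (low − high) and sojourn advantages in years.

## Velocity, competing risks, prediction, thresholds

**Person-time rates.** A pathway-specific rate counts that pathway's
subjects as events while every subject's risk time runs to their own first
confirmed event or censoring (all-cause risk time, the standard
first-event convention; the alternative — type-specific censoring — is not
what published person-year rates usually mean). Kaplan-Meier median time
to any confirmed decline uses `survival::survfit`. Velocity bands cut at
0.05 and 0.15 events/person-year, ties to the lower band. Annualized
decline slopes are per-subject OLS slopes of score on years, averaged per
pathway, with fold-ratios on absolute slopes against the stable pathway.

**Competing risks.** Event coding: 1 = direct conversion, 2 = first
confirmed MCI (MCI-only and MCI-to-dementia pooled at the first-event
time), 0 = censored. The Aalen-Johansen estimator and the Fine-Gray
partial-likelihood solver are implemented from first principles (these are
the methodological core), with `survival::coxph` as the reduction oracle
and `cmprsk::crr` as an independent cross-check in the tests. Fine-Gray
keeps competing-event subjects in the risk set with left-continuous
censoring-KM weights $G(t-)/G(T_j-)$; Newton-Raphson with Breslow ties,
converging when the score falls below $10^{-8}$ or the relative
log-likelihood change below $10^{-10}$. Time-varying covariates are out of
scope; baseline-covariate fits (optionally on landmark subsets) are the
supported analysis.

**Prediction.** Horizon outcomes at 12/24/36 months follow the
first-confirmed-event rule; subjects censored before a horizon without an
event are excluded from that horizon rather than imputed (the exclusion is
logged in the outputs). The multinomial model is softmax regression with
STABLE as reference, fitted by `nnet::multinom` under tight convergence
settings with an optional small L2 ridge for separation-prone designs.
Discrimination is one-vs-rest AUC by the Mann-Whitney rank statistic (ties
half credit), calibration by per-class Brier scores and Hosmer-Lemeshow
over probability deciles with bins merged to a minimum expected count of
5. Cross-validation is leakage-safe by construction: temporal splits train
strictly before an enrollment cutoff, and grouped k-fold partitions
subjects, never rows. In-sample and out-of-sample metrics are both
reported, and near-perfect single-biomarker AUCs should be read with the
usual suspicion of in-sample optimism.

**Thresholds.** ROC curves are empirical over all distinct cutpoints of
the negated z-score (the risk direction — lower metabolism, higher risk —
is fixed once for all contrasts); AUC is trapezoidal, equal to the rank
statistic. The Youden-optimal cutpoint maximizes $J = \text{sens} +
\text{spec} - 1$, ties broken toward the score median, and is reported on
the FDG z scale. Three contrasts are computed: stability vs any decline,
sequential vs direct among decliners, and direct vs all others. Individual
Youden cutpoints are sampling-noisy; tests therefore assert their expected
ordering across replicate cohorts rather than in any single cohort.

## The synthetic cohort generator

Because the source records cannot be redistributed, the generator is a
first-class, tested module that emulates their statistical structure:

* Baseline FDG z ~ N(0, 1); diagnosis trajectories follow an annual
  discrete-time Markov chain over CN/MCI/AD whose per-year transition
  probabilities are logistic in z (dementia absorbing).
* Visits are annual with uniform ±60-day jitter over up to ten years, and
  diagnoses are observed *only at visits*. This interval observation can
  skip a one-cycle MCI stage — deliberately, since direct conversion is
  defined on observed sequences; under the calibrated preset this artifact
  affects well under 5% of subjects.
* MMSE/ADAS follow linear trajectories with class-specific annual slopes
  (−0.52/−1.38/−2.90 and +0.91/+3.66/+6.26 points/year for the
  stable/MCI/dementia classes — MCI-to-dementia and direct converters
  share the dementia slopes), Gaussian visit noise, truncation to valid
  ranges. Baseline MMSE is truncated at 24 to respect CN screening.
* ADAS values are missing at 29.3% per visit and FDG at 36.2% per subject;
  FDG-missing subjects are excluded at eligibility (complete-case
  handling; imputation is out of scope).
* Centiloids are a 55/45 two-component Gaussian mixture (means 10/80, SDs
  15/30 — invented but documented; only separability matters for the
  mixture tests), coupled to a latent atrophy severity through a Gaussian
  copula targeting a weak rank correlation of 0.15, consistent with
  atrophy being a near-chance individual predictor of amyloid status.
* A per-visit dropout probability (default 0.06) ends follow-up
  geometrically. This field goes beyond the minimal generative story, but
  without it every stable subject would be censored at exactly ten years
  and censoring-dependent estimators would be exercised only degenerately.
* One seeded RNG stream per call; identical seeds give identical cohorts.

`default_params_paper_like()` is the calibrated preset (n = 1136): its
transition coefficients were chosen once so that classifier-derived
pathway proportions land near 32.8/34.9/15.8/16.5 percent with per-pathway
FDG means ordered stable > MCI-only > MCI-to-dementia > direct. The
published per-pathway FDG means cannot all be reproduced simultaneously —
weighted by the published proportions they average +0.31 rather than 0 on
a scale defined to have mean 0 over the same cohort — so the ordering, not
the values, is the calibration target.

What passing tests show, and do not show: the generator reproduces the
*structure* the estimators assume (Markov dynamics, logistic dose-response,
interval observation, missingness), so recovery and invariance tests
validate the estimators. It does not emulate site effects, diagnostic
drift, practice effects, tau biomarkers, or non-Markov dependence, so
agreement on synthetic data is not evidence about those features of real
cohorts.

## Numerical choices and degenerate inputs

Zero-variance FDG input errors; all-censored competing-risks data warn
and return zero incidence; an empty Markov stratum errors by name; empty
contrast arms and empty risk-table cells are reported missing, never
forced to zero. Zero cells in the 2×2 amyloid-by-atrophy table get the
Haldane-Anscombe 0.5 correction and are flagged. Ratios against a zero
reference rate error rather than returning infinities. One-decimal
rounding happens only at the reporting layer.

Problem sizes used by the test-suite and acceptance runs — ten preset
cohorts of 1136 for calibration, 2000 chains per stratum for Markov
recovery, ten replicates of n = 2000 for Fine-Gray recovery, bootstrap
B of 25-400 — were chosen as the smallest sizes at which Monte-Carlo error
is comfortably below the tested tolerances.

## Known limitations

* Sojourn times from a proper row-stochastic estimator are not comparable
  to published sojourn values computed from transition rows that do not
  sum to one (the residual mass there is unexplained); the package
  reproduces those values only as arithmetic on the published rows.
* The Fine-Gray implementation handles baseline covariates and Breslow
  ties only; no Gray's test, frailty terms, or time-varying weighting.
* Decline-risk bands for impaired baselines (MMSE 20-23, ADAS ≥ 30) are
  structurally empty in a cohort that is CN at baseline; they are reported
  with n = 0 rather than forced.
* The multinomial fit is deterministic given data, but `nnet` optimizer
  tolerances mean coefficients match an analytic oracle to ~4 decimals,
  not machine precision.
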