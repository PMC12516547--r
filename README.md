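# fdgpathways

Alzheimer's disease progression in cognitively normal older adults is not
one trajectory. Over a decade of follow-up, roughly a third of such
cohorts stay cognitively stable, a third progress to mild cognitive
impairment (MCI) and stop there, a smaller group passes through MCI to
dementia, and one in six converts *directly* from normal cognition to
dementia with no documented MCI stage. `fdgpathways` is an R package for
analyzing which pathway a person follows as a function of baseline brain
glucose metabolism (FDG-PET MetaROI composite, expressed as a cohort
z-score), for biostatisticians and imaging researchers working with
ADNI-style longitudinal diagnosis tables.

The package implements, end to end:

* **Pathway classification** of longitudinal CN/MCI/AD diagnosis
  sequences into four pathways (stable, MCI-only, MCI-to-dementia, direct
  conversion), with 180-day confirmation smoothing of diagnostic
  fluctuation, event times and censoring.
* **Metabolic indices**: FDG z-scores, tertiles and fixed ±0.5 risk
  categories, cognitive reserve (MMSE − ADAS/3), a metabolic-cognitive
  vulnerability score, amyloid positivity by a two-component Gaussian
  mixture (EM), a PCA atrophy index, and a composite vulnerability index.
* **Discrete-time Markov modeling**: per-stratum annual transition
  matrices `p̂_ij = n_ij / Σ_j n_ij` over {CN, MCI, AD} (dementia
  absorbing), geometric sojourn times `1/(1 − p_stay)`, and
  low-vs-high-metabolism contrasts.
* **Pathway velocity**: person-time incidence rates per 100 person-years,
  acceleration ratios against the high-metabolism stratum, Kaplan-Meier
  median time to decline, velocity risk bands, and annualized MMSE/ADAS
  decline slopes with fold-ratios.
* **Competing risks**: the Aalen-Johansen cumulative incidence estimator
  `F_k(t) = Σ_{t_i ≤ t} S(t_i−) d_ki / n_i` and Fine-Gray
  subdistribution-hazard regression (Newton-Raphson on the weighted
  partial likelihood, Breslow ties), both implemented from first
  principles and cross-checked against `survival` and `cmprsk` oracles.
* **Multinomial pathway prediction** at 12/24/36-month horizons from
  baseline FDG (± cognition), with one-vs-rest AUC, Brier scores,
  Hosmer-Lemeshow calibration, temporal-split and subject-grouped k-fold
  cross-validation.
* **Threshold discovery**: empirical ROC curves and Youden-optimal FDG
  z cutpoints (J = sensitivity + specificity − 1) for three decision
  contrasts, plus dose-response bins.
* A **seeded synthetic-cohort generator** emulating ADNI-style subject
  and visit tables (annual Markov diagnosis dynamics logistic in FDG z,
  jittered visit schedules, score trajectories, missingness, bimodal
  centiloids), so the whole pipeline is testable without restricted data.

See `vignettes/pathway-methods.Rmd` for the model assumptions, design
decisions and limitations.

## Worked example

```r
library(fdgpathways)

sim  <- simulate_cohort(default_params_paper_like(seed = 1))
x    <- eligibility_filter(sim$cohort)$cohort      # 723 of 1136 eligible
asg  <- classify_cohort(x)
idx  <- compute_indices(x)

pathway_summary(asg, setNames(idx$fdg_z, idx$subject_id))$table
#>             n    pct fdg_mean fdg_sd
#> STABLE    240 33.195    0.307  0.969
#> MCI_ONLY  242 33.472    0.112  0.995
#> MCI_TO_AD 129 17.842   -0.206  0.879
#> DIRECT_AD 112 15.491   -0.663  0.849
```

A third of the cohort stays stable, direct converters are the most
hypometabolic group, and baseline FDG falls monotonically from the stable
to the direct pathway (a 0.97 SD gradient in this cohort).

```r
velocity_analysis(asg, idx)[, c("tertile", "direct_rate_per_100py",
                                "direct_acceleration",
                                "median_any_decline_years")]
#>   tertile direct_rate_per_100py direct_acceleration median_any_decline_years
#> 1    HIGH                  1.26                1.00                     6.12
#> 2     MID                  2.95                2.35                     4.96
#> 3     LOW                  7.14                5.69                     3.12
```

Direct conversion runs at 1.3 events per 100 person-years in the
preserved-metabolism tertile versus 7.1 in the hypometabolic tertile — a
5.7-fold acceleration — and the median time to any confirmed decline
halves from 6.1 to 3.1 years.

```r
cr <- competing_risks_data(asg, idx)
fine_gray_fit(cr$time, cr$event, matrix(cr$fdg_z, ncol = 1))
#> Fine-Gray subdistribution hazard fit
#>         coef exp(coef)         se
#> 1 -0.7725721 0.4618237 0.09598904
```

Each SD of higher baseline metabolism roughly halves the subdistribution
hazard of direct conversion (sdHR 0.46).

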