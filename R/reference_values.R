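#' Benchmark estimates from the originating ADNI cohort analysis
#'
#' Point estimates reported by the FDG-PET pathway analysis this package
#' operationalizes, kept here as inputs for worked-example arithmetic
#' (sojourn times, acceleration ratios, metabolic gradients, decline
#' fold-ratios) and for consistency checks.  These are published summary
#' numbers, not data: the underlying ADNI records are not redistributable,
#' which is why the package ships a synthetic-cohort generator instead.
#'
#' Components:
#' \describe{
#'   \item{transition}{annual transition probabilities by FDG stratum
#'     (high/mid/low): `cn_cn`, `cn_mci`, `cn_ad`, `mci_mci`, `mci_ad`.}
#'   \item{direct_rate_per_100py, mci_rate_per_100py}{pathway incidence
#'     rates per 100 person-years by stratum.}
#'   \item{event_rate_per_py}{all-decline event rates per person-year.}
#'   \item{median_decline_years}{median time to any decline by stratum.}
#'   \item{fdg_means}{per-pathway baseline FDG z means (stable, MCI-only,
#'     MCI-to-AD, direct).}
#'   \item{pathway_pct}{per-pathway percentages.}
#'   \item{mmse_slopes, adas_slopes}{annual score change for the stable /
#'     MCI / dementia trajectory classes (points/year).}
#'   \item{youden}{sensitivity/specificity pairs at the reported decision
#'     thresholds.}
#' }
#'
#' @format a named list.
#' @export
reference_estimates <- list(
  transition = list(
    high = c(cn_cn = 0.429, cn_mci = 0.376, cn_ad = 0.090,
             mci_mci = 0.780, mci_ad = 0.220),
    mid = c(cn_cn = 0.302, cn_mci = 0.385, cn_ad = 0.145,
            mci_mci = 0.695, mci_ad = 0.305),
    low = c(cn_cn = 0.160, cn_mci = 0.222, cn_ad = 0.369,
            mci_mci = 0.472, mci_ad = 0.528)),
  direct_rate_per_100py = c(high = 2.31, mid = 4.02, low = 17.12),
  mci_rate_per_100py = c(high = 12.48, mid = 18.90, low = 27.39),
  event_rate_per_py = c(high = 0.571, mid = 0.698, low = 0.840),
  median_decline_years = c(high = 6.2, mid = 4.8, low = 2.9),
  fdg_means = c(stable = 0.57, mci_only = 0.43, mci_to_ad = 0.04,
                direct = -0.18),
  pathway_pct = c(stable = 32.8, mci_only = 34.9, mci_to_ad = 15.8,
                  direct = 16.5),
  mmse_slopes = c(stable = -0.52, mci = -1.38, ad = -2.90),
  adas_slopes = c(stable = 0.91, mci = 3.66, ad = 6.26),
  youden = list(
    stability_vs_decline = c(cutpoint = 0.50, sensitivity = 0.73,
                             specificity = 0.68),
    direct_high_risk = c(cutpoint = -0.50, sensitivity = 0.78,
                         specificity = 0.82)))
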