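# Person-time incidence rates per pathway and FDG stratum, acceleration
# ratios, Kaplan-Meier medians, velocity risk bands, and annualized
# cognitive-decline slopes.

DAYS_PER_YEAR <- 365.25

#' Person-time incidence rate of a pathway within a stratum
#'
#' Events are subjects in the stratum whose pathway label matches
#' `event_label`; person-time for every subject in the stratum runs to their
#' own first confirmed event or censoring (all-cause risk-time, the standard
#' first-event convention).
#'
#' @param assignments data.frame from [classify_cohort()].
#' @param strata named vector of stratum labels (names = subject_id).
#' @param stratum stratum to evaluate.
#' @param event_label pathway counting as the event (e.g. `"DIRECT_AD"`).
#' @return list: `events`, `person_years`, `rate_per_100py`.
#' @export
incidence_rate <- function(assignments, strata, stratum, event_label) {
  in_s <- strata[assignments$subject_id] == stratum & !is.na(
    strata[assignments$subject_id])
  if (!any(in_s)) stop("empty stratum: ", stratum)
  a <- assignments[in_s, ]
  t_days <- ifelse(is.na(a$t_first_event_days), a$t_censor_days,
                   a$t_first_event_days)
  py <- sum(t_days) / DAYS_PER_YEAR
  if (py <= 0) stop("zero person-years in stratum ", stratum)
  events <- sum(a$label == event_label)
  list(events = events, person_years = py,
       rate_per_100py = 100 * events / py)
}

#' Acceleration ratios of stratum rates against a reference stratum
#'
#' @param rates named numeric vector of rates (per 100 person-years).
#' @param reference name of the reference stratum (default `"HIGH"`).
#' @return named numeric vector of `rate / reference rate`.
#' @export
acceleration_table <- function(rates, reference = "HIGH") {
  stopifnot(reference %in% names(rates))
  if (rates[[reference]] <= 0) {
    stop("reference rate is zero: ratios undefined")
  }
  rates / rates[[reference]]
}

#' Kaplan-Meier median time to any confirmed decline
#'
#' @param time_years time to first confirmed decline or censoring (years).
#' @param event logical/0-1: any confirmed decline observed.
#' @return list: `median_years` (NA when survival never reaches 0.5,
#'   reported as not reached), `events`, `person_years`,
#'   `event_rate_per_py`, `fit` (the `survfit` object).
#' @export
km_median_time <- function(time_years, event) {
  stopifnot(length(time_years) == length(event))
  if (sum(event) < 1) stop("need >= 1 event")
  fit <- survival::survfit(survival::Surv(time_years, event) ~ 1)
  med <- unname(summary(fit)$table["median"])
  list(median_years = med,
       events = sum(event),
       person_years = sum(time_years),
       event_rate_per_py = sum(event) / sum(time_years),
       fit = fit)
}

#' Velocity risk band of an event rate
#'
#' Bands at 0.05 and 0.15 events per person-year; boundary ties go to the
#' lower band.
#'
#' @param rate events per person-year (>= 0).
#' @return factor over LOW/MODERATE/HIGH.
#' @export
velocity_band <- function(rate) {
  stopifnot(all(rate >= 0, na.rm = TRUE))
  factor(ifelse(rate <= 0.05, "LOW",
         ifelse(rate <= 0.15, "MODERATE", "HIGH")),
         levels = c("LOW", "MODERATE", "HIGH"))
}

#' Annualized cognitive-decline slopes by pathway
#'
#' Per-subject least-squares slope of score against years from baseline
#' (subjects with fewer than two non-missing scores are excluded and
#' logged), averaged by pathway; fold-ratios are absolute slopes relative to
#' the stable pathway.
#'
#' @param x a [cohort()] object.
#' @param assignments data.frame from [classify_cohort()].
#' @param score `"mmse"` or `"adas"`.
#' @return list: `slopes` (per-pathway data.frame with n, mean_slope, sd,
#'   fold_vs_stable), `per_subject` (subject_id, slope), `excluded`
#'   (subject ids without two scored visits).
#' @export
annual_decline_slopes <- function(x, assignments, score = c("mmse", "adas")) {
  score <- match.arg(score)
  vs <- split(x$visits, x$visits$subject_id)
  ids <- assignments$subject_id
  slope <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    v <- vs[[ids[i]]]
    y <- v[[score]]
    ok <- !is.na(y)
    if (sum(ok) < 2) next
    t <- v$day[ok] / DAYS_PER_YEAR
    yy <- y[ok]
    if (stats::var(t) == 0) next
    slope[i] <- stats::cov(t, yy) / stats::var(t)
  }
  excluded <- ids[is.na(slope)]
  grp <- factor(assignments$label, levels = PATHWAY_LEVELS)
  agg <- function(f) vapply(levels(grp), function(g) {
    v <- slope[grp == g & !is.na(slope)]
    if (length(v)) f(v) else NA_real_
  }, numeric(1))
  mean_slope <- agg(mean)
  tab <- data.frame(
    pathway = PATHWAY_LEVELS,
    n = vapply(levels(grp),
               function(g) sum(grp == g & !is.na(slope)), integer(1)),
    mean_slope = mean_slope,
    sd_slope = agg(stats::sd),
    fold_vs_stable = abs(mean_slope) / abs(mean_slope[1]),
    row.names = NULL, stringsAsFactors = FALSE)
  list(slopes = tab,
       per_subject = data.frame(subject_id = ids, slope = slope,
                                stringsAsFactors = FALSE),
       excluded = excluded)
}

#' Velocity analysis across FDG tertiles
#'
#' Computes, per tertile: direct-conversion and MCI-first incidence rates
#' with acceleration ratios against the high-metabolism tertile, the
#' Kaplan-Meier median time to any confirmed decline, the all-decline event
#' rate per person-year, and its velocity band.
#'
#' @param assignments data.frame from [classify_cohort()].
#' @param indices data.frame from [compute_indices()].
#' @return data.frame keyed by tertile.
#' @export
velocity_analysis <- function(assignments, indices) {
  strata <- stats::setNames(as.character(indices$tertile),
                            indices$subject_id)
  terts <- c("HIGH", "MID", "LOW")
  rows <- lapply(terts, function(g) {
    direct <- incidence_rate(assignments, strata, g, "DIRECT_AD")
    mci <- list(
      events = sum(assignments$label %in% c("MCI_ONLY", "MCI_TO_AD") &
                     strata[assignments$subject_id] == g, na.rm = TRUE),
      person_years = direct$person_years)
    in_s <- strata[assignments$subject_id] == g &
      !is.na(strata[assignments$subject_id])
    a <- assignments[in_s, ]
    t_years <- ifelse(is.na(a$t_first_event_days), a$t_censor_days,
                      a$t_first_event_days) / DAYS_PER_YEAR
    ev <- a$label != "STABLE"
    km <- km_median_time(t_years, ev)
    data.frame(
      tertile = g, n = nrow(a),
      direct_rate_per_100py = direct$rate_per_100py,
      mci_rate_per_100py = 100 * mci$events / mci$person_years,
      median_any_decline_years = km$median_years,
      event_rate_per_py = km$event_rate_per_py,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$direct_acceleration <- out$direct_rate_per_100py /
    out$direct_rate_per_100py[out$tertile == "HIGH"]
  out$mci_acceleration <- out$mci_rate_per_100py /
    out$mci_rate_per_100py[out$tertile == "HIGH"]
  out$velocity_band <- velocity_band(out$event_rate_per_py)
  out
}
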