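# Seeded generative model for ADNI-style subject/visit tables.  Diagnosis
# trajectories follow a discrete-time annual Markov chain over CN/MCI/AD whose
# per-year transition probabilities are logistic in the subject's baseline FDG
# z-score; AD is absorbing.  Cognitive scores follow linear trajectories with
# pathway-specific annual slopes plus noise.  Diagnoses are observed only at
# jittered visit dates (interval observation), so an MCI stage lasting a
# single cycle can be skipped — deliberately, since direct conversion is
# defined on observed sequences.

#' Construct simulation parameters for the synthetic cohort generator
#'
#' Defaults encode the study conditions the analysis assumes: annual visits
#' with uniform +/-60-day jitter over up to ten years of follow-up, baseline
#' FDG on the z scale, annual transition probabilities logistic in FDG z,
#' pathway-specific MMSE/ADAS annual slopes (-0.52/-1.38/-2.90 and
#' +0.91/+3.66/+6.26 points per year for the stable / MCI / dementia
#' trajectory classes), 29.3% visit-level ADAS missingness and 36.2%
#' subject-level FDG missingness, a bimodal centiloid distribution, and weak
#' amyloid-atrophy coupling.
#'
#' @param n_subjects number of subjects to generate.
#' @param seed RNG seed used by [simulate_cohort()].
#' @param visit_interval_days mean visit spacing in days.
#' @param visit_jitter_days half-width of the uniform visit-day jitter.
#' @param max_followup_days maximum scheduled follow-up (ten years).
#' @param dropout_prob per-visit probability of ending follow-up after the
#'   visit (geometric dropout; baseline visit always observed).
#' @param fdg_mean,fdg_sd location and scale of raw MetaROI values; the
#'   generator's internal z-score is `(fdg_raw - fdg_mean)/fdg_sd`.
#' @param transition_coeffs list with elements `cn_mci`, `cn_ad`, `mci_ad`,
#'   each `c(intercept, slope)` on the logit scale for the corresponding
#'   annual transition probability as a function of FDG z (negative slope =
#'   higher metabolism protects).
#' @param mmse_slopes,adas_slopes named length-3 vectors (`stable`, `mci`,
#'   `ad`) of annual score change by latent trajectory class.
#' @param mmse_baseline_mean,mmse_baseline_sd,adas_baseline_mean,adas_baseline_sd
#'   baseline score distributions (MMSE truncated to 24..30 so baselines meet
#'   CN screening criteria; ADAS truncated at 0).
#' @param noise_sd_mmse,noise_sd_adas visit-level Gaussian score noise (points).
#' @param missing_rate_adas per-visit ADAS missingness probability.
#' @param missing_rate_fdg per-subject FDG missingness probability.
#' @param centiloid_mixture list(weights, means, sds) for the two-component
#'   Gaussian centiloid mixture (first component = amyloid-negative mode).
#' @param atrophy_amyloid_rho target rank correlation between the latent
#'   atrophy severity and centiloid burden.
#' @param age_mean,age_sd baseline age distribution (truncated at 55).
#' @param enroll_window_days enrollment dates are uniform on
#'   `0..enroll_window_days` (used for temporal cross-validation splits).
#' @return an object of class `"simulation_params"`.
#' @export
simulation_params <- function(n_subjects = 500,
                              seed = 1L,
                              visit_interval_days = 365,
                              visit_jitter_days = 60,
                              max_followup_days = 3652,
                              dropout_prob = 0.06,
                              fdg_mean = 0,
                              fdg_sd = 1,
                              transition_coeffs = list(
                                cn_mci = c(-2.10, -0.35),
                                cn_ad  = c(-3.60, -1.15),
                                mci_ad = c(-2.35, -0.90)),
                              mmse_slopes = c(stable = -0.52, mci = -1.38,
                                              ad = -2.90),
                              adas_slopes = c(stable = 0.91, mci = 3.66,
                                              ad = 6.26),
                              mmse_baseline_mean = 28.5,
                              mmse_baseline_sd = 1.1,
                              adas_baseline_mean = 8,
                              adas_baseline_sd = 3,
                              noise_sd_mmse = 1.2,
                              noise_sd_adas = 2.5,
                              missing_rate_adas = 0.293,
                              missing_rate_fdg = 0.362,
                              centiloid_mixture = list(
                                weights = c(0.55, 0.45),
                                means = c(10, 80),
                                sds = c(15, 30)),
                              atrophy_amyloid_rho = 0.15,
                              age_mean = 73,
                              age_sd = 6,
                              enroll_window_days = 1825) {
  stopifnot(n_subjects >= 1, fdg_sd > 0, noise_sd_mmse > 0, noise_sd_adas > 0,
            missing_rate_adas >= 0, missing_rate_adas <= 1,
            missing_rate_fdg >= 0, missing_rate_fdg <= 1,
            dropout_prob >= 0, dropout_prob < 1,
            abs(sum(centiloid_mixture$weights) - 1) < 1e-8,
            all(centiloid_mixture$sds > 0))
  p <- as.list(environment())
  structure(p, class = "simulation_params")
}

#' Calibrated paper-like simulation preset
#'
#' Returns [simulation_params()] at n = 1136 with transition coefficients
#' calibrated so that classifier-derived pathway proportions land near
#' 32.8/34.9/15.8/16.5 percent (stable / MCI-only / MCI-to-dementia / direct)
#' and per-pathway mean FDG z is ordered stable > MCI-only > MCI-to-dementia
#' > direct.
#'
#' @param n_subjects cohort size (default 1136).
#' @param seed RNG seed.
#' @return a `"simulation_params"` object.
#' @export
default_params_paper_like <- function(n_subjects = 1136, seed = 42L) {
  simulation_params(
    n_subjects = n_subjects,
    seed = seed,
    transition_coeffs = list(
      cn_mci = c(-1.75, -0.28),
      cn_ad  = c(-3.60, -1.30),
      mci_ad = c(-2.30, -0.40)))
}

#' Annual transition matrix implied by generator coefficients at a given z
#'
#' Evaluates the generating logistic transition model at FDG z-score `z`,
#' returning the 3x3 annual matrix over (CN, MCI, AD) with AD absorbing.
#' Competing CN exit probabilities are rescaled proportionally if their sum
#' exceeds 1 (degenerate coefficient regime).
#'
#' @param params a `"simulation_params"` object.
#' @param z FDG z-score (scalar).
#' @return 3x3 row-stochastic matrix with dimnames CN/MCI/AD.
#' @export
transition_matrix_at_z <- function(params, z) {
  tc <- params$transition_coeffs
  p_cm <- stats::plogis(tc$cn_mci[1] + tc$cn_mci[2] * z)
  p_ca <- stats::plogis(tc$cn_ad[1] + tc$cn_ad[2] * z)
  if (p_cm + p_ca > 1) {
    s <- p_cm + p_ca
    p_cm <- p_cm / s
    p_ca <- p_ca / s
  }
  p_ma <- stats::plogis(tc$mci_ad[1] + tc$mci_ad[2] * z)
  m <- rbind(c(max(0, 1 - p_cm - p_ca), p_cm, p_ca),
             c(0, 1 - p_ma, p_ma),
             c(0, 0, 1))
  dimnames(m) <- list(DIAGNOSIS_LEVELS, DIAGNOSIS_LEVELS)
  m
}

# Inverse-CDF draw from the 2-component Gaussian mixture driven by a single
# uniform, so that larger u gives (component-wise) larger centiloid -- the
# Gaussian-copula hook for amyloid-atrophy coupling.
.centiloid_from_uniform <- function(u, mix) {
  w1 <- mix$weights[1]
  ifelse(u < w1,
         stats::qnorm(pmin(pmax(u / w1, 1e-12), 1 - 1e-12),
                      mix$means[1], mix$sds[1]),
         stats::qnorm(pmin(pmax((u - w1) / (1 - w1), 1e-12), 1 - 1e-12),
                      mix$means[2], mix$sds[2]))
}

#' Simulate a synthetic longitudinal cohort
#'
#' Generates subject and visit tables per the generative model in
#' [simulation_params()], together with the ground truth needed for recovery
#' tests.  Identical seeds give identical output.
#'
#' @param params a `"simulation_params"` object.
#' @return list with elements `cohort` (a [cohort()]) and `truth` (list:
#'   `subjects` data.frame with `subject_id`, `z_true`, `latent_pathway`;
#'   `coeffs` the generating transition coefficients).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  n <- params$n_subjects
  cycle <- 365L
  n_cycles <- floor(params$max_followup_days / cycle)

  ids <- sprintf("S%04d", seq_len(n))
  z <- stats::rnorm(n)
  fdg_raw <- params$fdg_mean + params$fdg_sd * z
  fdg_raw[stats::runif(n) < params$missing_rate_fdg] <- NA_real_
  age <- pmax(55, round(stats::rnorm(n, params$age_mean, params$age_sd), 1))
  enroll <- sample.int(params$enroll_window_days + 1L, n, replace = TRUE) - 1L

  # amyloid & atrophy via a Gaussian copula on (centiloid, atrophy severity)
  rho <- 2 * sin(pi * params$atrophy_amyloid_rho / 6)
  e1 <- stats::rnorm(n)
  e2 <- rho * e1 + sqrt(1 - rho^2) * stats::rnorm(n)
  centiloid <- .centiloid_from_uniform(stats::pnorm(e1),
                                       params$centiloid_mixture)
  hippocampus <- pmax(3000, 7400 - 500 * e2 + stats::rnorm(n, 0, 250))
  brain <- pmax(8e5, 1.06e6 - 15000 * e2 + stats::rnorm(n, 0, 30000))

  if (transition_matrix_at_z(params, 0)["CN", "CN"] <= 0) {
    warning("degenerate transition coefficients: all CN exits certain ",
            "for a typical (z = 0) subject")
  }
  visit_rows <- vector("list", n)
  latent <- character(n)
  for (i in seq_len(n)) {
    tm <- transition_matrix_at_z(params, z[i])
    # true annual state path at anniversaries 0..n_cycles
    states <- integer(n_cycles + 1L)
    states[1] <- 1L
    for (k in seq_len(n_cycles)) {
      s <- states[k]
      states[k + 1L] <- if (s == 3L) 3L else
        sample.int(3L, 1L, prob = tm[s, ])
    }
    latent[i] <-
      if (all(states == 1L)) "STABLE"
      else if (!any(states == 3L)) "MCI_ONLY"
      else if (any(states == 2L)) "MCI_TO_AD"
      else "DIRECT_AD"

    # jittered visit schedule with geometric dropout
    sched <- seq(params$visit_interval_days, params$max_followup_days,
                 by = params$visit_interval_days)
    jit <- round(stats::runif(length(sched), -params$visit_jitter_days,
                              params$visit_jitter_days))
    days <- c(0L, as.integer(sched + jit))
    days <- days[days <= params$max_followup_days]
    days <- days[!duplicated(days)]
    drop_after <- which(stats::runif(length(days)) < params$dropout_prob)
    drop_after <- drop_after[drop_after > 1L]
    if (length(drop_after)) days <- days[seq_len(min(drop_after))]

    obs_state <- states[pmin(floor(days / cycle), n_cycles) + 1L]
    cls <- switch(latent[i], STABLE = "stable", MCI_ONLY = "mci", "ad")
    yrs <- days / 365.25
    mmse <- round(stats::rnorm(1, params$mmse_baseline_mean,
                               params$mmse_baseline_sd) +
                  params$mmse_slopes[[cls]] * yrs +
                  stats::rnorm(length(days), 0, params$noise_sd_mmse))
    mmse <- pmin(30L, pmax(0L, as.integer(mmse)))
    mmse[1] <- max(mmse[1], 24L)  # CN screening criterion at baseline
    adas <- round(stats::rnorm(1, params$adas_baseline_mean,
                               params$adas_baseline_sd) +
                  params$adas_slopes[[cls]] * yrs +
                  stats::rnorm(length(days), 0, params$noise_sd_adas), 1)
    adas <- pmax(0, adas)
    adas[stats::runif(length(days)) < params$missing_rate_adas] <- NA_real_

    visit_rows[[i]] <- data.frame(
      subject_id = ids[i], day = days,
      diagnosis = DIAGNOSIS_LEVELS[obs_state],
      mmse = mmse, adas = adas, stringsAsFactors = FALSE)
  }

  subjects <- data.frame(
    subject_id = ids, age_baseline = age, fdg_raw = fdg_raw,
    centiloid = centiloid, hippocampus_vol = hippocampus,
    brain_vol = brain, enroll_day = enroll, stringsAsFactors = FALSE)
  visits <- do.call(rbind, visit_rows)
  list(cohort = cohort(subjects, visits),
       truth = list(subjects = data.frame(subject_id = ids, z_true = z,
                                          latent_pathway = latent,
                                          stringsAsFactors = FALSE),
                    coeffs = params$transition_coeffs))
}

#' Write simulator ground truth to a JSON sidecar
#'
#' @param truth the `truth` element returned by [simulate_cohort()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(subjects = truth$subjects, coeffs = truth$coeffs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
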