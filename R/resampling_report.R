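# Bootstrap / Monte-Carlo utilities and the pipeline orchestrator.

#' Subject-level bootstrap confidence interval
#'
#' Resamples subjects with replacement (visits travel with their subject),
#' recomputes the statistic on each replicate, and reports percentile and
#' bias-corrected (BC, no acceleration) 95% intervals.
#'
#' @param statistic function taking a [cohort()] and returning a scalar.
#' @param x a [cohort()] object.
#' @param B number of replicates (default 1000).
#' @param seed RNG seed.
#' @return list: `point`, `B`, `replicates`, `ci_percentile`, `ci_bc`,
#'   `degenerate` (TRUE when B = 1), `n_failed`.
#' @export
bootstrap_ci <- function(statistic, x, B = 1000, seed = 1L) {
  stopifnot(inherits(x, "cohort"), B >= 1)
  point <- statistic(x)
  set.seed(seed)
  vs <- split(x$visits, x$visits$subject_id)
  n <- nrow(x$subjects)
  reps <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    subs <- x$subjects[idx, , drop = FALSE]
    new_ids <- sprintf("B%05d", seq_len(n))
    vlist <- lapply(seq_len(n), function(i) {
      v <- vs[[subs$subject_id[i]]]
      v$subject_id <- new_ids[i]
      v
    })
    subs$subject_id <- new_ids
    xb <- cohort(subs, do.call(rbind, vlist))
    reps[b] <- tryCatch(statistic(xb), error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.1 * B) {
    stop("statistic failed on ", n_failed, " of ", B,
         " bootstrap replicates")
  }
  good <- reps[!is.na(reps)]
  if (B == 1) {
    warning("B = 1: degenerate interval equal to the single replicate")
    return(list(point = point, B = B, replicates = reps,
                ci_percentile = rep(good, 2), ci_bc = rep(good, 2),
                degenerate = TRUE, n_failed = n_failed))
  }
  ci_pct <- stats::quantile(good, c(0.025, 0.975), names = FALSE)
  # bias correction: z0 from the fraction of replicates below the point
  frac <- mean(good < point)
  frac <- min(max(frac, 1 / (length(good) + 1)),
              length(good) / (length(good) + 1))
  z0 <- stats::qnorm(frac)
  a_lo <- stats::pnorm(2 * z0 + stats::qnorm(0.025))
  a_hi <- stats::pnorm(2 * z0 + stats::qnorm(0.975))
  ci_bc <- stats::quantile(good, c(a_lo, a_hi), names = FALSE)
  list(point = point, B = B, replicates = reps,
       ci_percentile = ci_pct, ci_bc = ci_bc,
       degenerate = FALSE, n_failed = n_failed)
}

#' Monte-Carlo stability of key pipeline estimates
#'
#' Repeats simulate-then-analyze cycles and summarizes the spread of three
#' key estimates: the direct-conversion acceleration ratio (low vs high FDG
#' tertile), the direct-conversion one-vs-rest ROC AUC, and the Youden
#' cutpoint of the direct-vs-rest contrast.  The stability index is
#' `1 - coefficient of variation`, clipped to `[0, 1]`.
#'
#' @param params a `"simulation_params"` object (its seed is re-derived per
#'   replicate from `seed`).
#' @param reps number of Monte-Carlo replicates (default 200).
#' @param seed master RNG seed.
#' @return list: `estimates` (reps x 3 matrix), `summary` (mean, sd, MC
#'   standard error, stability index per estimate).
#' @export
monte_carlo_stability <- function(params, reps = 200, seed = 1L) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  est <- matrix(NA_real_, reps, 3,
                dimnames = list(NULL, c("direct_acceleration", "direct_auc",
                                        "direct_cutpoint")))
  for (r in seq_len(reps)) {
    p <- params
    p$seed <- rep_seeds[r]
    res <- tryCatch({
      sim <- simulate_cohort(p)
      elig <- eligibility_filter(sim$cohort)$cohort
      asg <- classify_cohort(elig)
      idx <- compute_indices(elig)
      vel <- velocity_analysis(asg, idx)
      z <- stats::setNames(idx$fdg_z, idx$subject_id)
      cs <- contrast_suite(asg, z)
      c(vel$direct_acceleration[vel$tertile == "LOW"],
        cs$auc[cs$contrast == "direct_vs_rest"],
        cs$cutpoint_z[cs$contrast == "direct_vs_rest"])
    }, error = function(e) rep(NA_real_, 3))
    est[r, ] <- res
  }
  mu <- colMeans(est, na.rm = TRUE)
  sdv <- apply(est, 2, stats::sd, na.rm = TRUE)
  n_ok <- colSums(!is.na(est))
  list(estimates = est,
       summary = data.frame(
         estimate = colnames(est), mean = mu, sd = sdv,
         mc_se = sdv / sqrt(pmax(n_ok, 1)),
         stability_index = pmin(pmax(1 - sdv / abs(mu), 0), 1),
         row.names = NULL, stringsAsFactors = FALSE))
}

#' Run the full pathway pipeline and write a report bundle
#'
#' Orchestrates simulate/read, eligibility, classification, indices, Markov,
#' velocity, competing risks, prediction, threshold discovery and the
#' bootstrap, writing every module output plus a single JSON report to
#' `out_dir`.  Identical config and seed give byte-identical outputs.
#'
#' @param config list with elements: either `params` (a
#'   `"simulation_params"`) or `subject_path`/`visit_path` (CSV inputs);
#'   `out_dir`; optional `seed` (overrides `params$seed`), `horizons`
#'   (months, default c(12, 24, 36)), `B` (bootstrap replicates, default
#'   200), `min_confirm_days` (default 180), `kfold` (default 5).
#' @return invisibly, the report list.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  horizons <- config$horizons %||% c(12, 24, 36)
  B <- config$B %||% 200
  mcd <- config$min_confirm_days %||% 180
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  report <- list(settings = list(horizons = horizons, B = B,
                                 min_confirm_days = mcd))
  tryCatch({
    if (!is.null(config$params)) {
      p <- config$params
      if (!is.null(config$seed)) p$seed <- config$seed
      sim <- simulate_cohort(p)
      x <- sim$cohort
      write_cohort(x, file.path(config$out_dir, "subjects.csv"),
                   file.path(config$out_dir, "visits.csv"))
      write_ground_truth(sim$truth,
                         file.path(config$out_dir, "ground_truth.json"))
    } else {
      for (pth in c(config$subject_path, config$visit_path)) {
        if (!file.exists(pth)) stop("input file not found: ", pth)
      }
      x <- read_cohort(config$subject_path, config$visit_path)
    }

    stage <- "eligibility"
    elig <- eligibility_filter(x)
    report$counts <- list(input = nrow(x$subjects),
                          eligible = nrow(elig$cohort$subjects),
                          excluded = nrow(elig$exclusions))
    x <- elig$cohort

    stage <- "classify"
    asg <- classify_cohort(x, min_confirm_days = mcd)
    write_assignments(asg, file.path(config$out_dir, "assignments.csv"))

    stage <- "indices"
    idx <- compute_indices(x)
    utils::write.csv(idx, file.path(config$out_dir, "indices.csv"),
                     row.names = FALSE, na = "")
    z <- stats::setNames(idx$fdg_z, idx$subject_id)

    stage <- "summary"
    summ <- pathway_summary(asg, z,
                            stats::setNames(idx$cognitive_reserve,
                                            idx$subject_id),
                            stats::setNames(idx$vulnerability_index,
                                            idx$subject_id))
    report$pathways <- summ

    stage <- "markov"
    mk <- markov_analysis(x, idx, min_confirm_days = mcd)
    report$markov <- list(
      P = lapply(mk$matrices, function(m) m$P),
      sojourns = mk$sojourns, contrasts = mk$contrasts)
    jsonlite::write_json(report$markov,
                         file.path(config$out_dir, "markov.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)

    stage <- "velocity"
    vel <- velocity_analysis(asg, idx)
    utils::write.csv(vel, file.path(config$out_dir, "velocity.csv"),
                     row.names = FALSE, na = "")
    report$velocity <- vel
    for (sc in c("mmse", "adas")) {
      report[[paste0("slopes_", sc)]] <-
        annual_decline_slopes(x, asg, sc)$slopes
    }

    stage <- "competing_risks"
    cr <- competing_risks_data(asg, idx)
    report$cif <- tryCatch({
      aj <- aalen_johansen(cr$time, cr$event)
      list(f_direct_5y = cif_at(aj, 5, 1), f_mci_5y = cif_at(aj, 5, 2))
    }, error = function(e) NULL)
    report$fine_gray <- tryCatch({
      fit <- fine_gray_fit(cr$time, cr$event, matrix(cr$fdg_z, ncol = 1))
      list(coef = fit$coef, shr = fit$shr, se = fit$se,
           converged = fit$converged)
    }, error = function(e) list(error = conditionMessage(e)))
    jsonlite::write_json(report$fine_gray,
                         file.path(config$out_dir, "finegray.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)

    stage <- "prediction"
    pred <- list()
    for (h in horizons) {
      oc <- build_horizon_outcomes(asg, h)
      fit <- tryCatch(fit_multinomial(oc, idx), error = function(e) NULL)
      if (is.null(fit)) next
      pred[[as.character(h)]] <- list(
        evaluation = evaluate_predictions(fit, oc, idx),
        n_known = sum(oc$known))
      if (h == 24) {
        report$fdg_probability_table <- probability_by_fdg_category(fit)
        report$decision_bands <- decision_bands(fit)
      }
    }
    report$prediction <- pred
    jsonlite::write_json(pred, file.path(config$out_dir, "predict.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)

    stage <- "thresholds"
    thr <- contrast_suite(asg, z)
    report$thresholds <- thr
    jsonlite::write_json(thr, file.path(config$out_dir, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.csv(dose_response_bins(z, asg),
                     file.path(config$out_dir, "doseresponse.csv"),
                     row.names = FALSE, na = "")

    stage <- "risk_table"
    report$risk_table <- decline_risk_table(x, idx)

    stage <- "bootstrap"
    if (B > 0) {
      boot_stat <- function(xb) {
        a <- classify_cohort(xb, min_confirm_days = mcd)
        i <- compute_indices(xb)
        s <- stats::setNames(as.character(i$tertile), i$subject_id)
        lo <- incidence_rate(a, s, "LOW", "DIRECT_AD")
        hi <- incidence_rate(a, s, "HIGH", "DIRECT_AD")
        lo$rate_per_100py / hi$rate_per_100py
      }
      report$bootstrap_direct_ratio <- tryCatch({
        bc <- bootstrap_ci(boot_stat, x, B = B,
                           seed = config$seed %||% 1L)
        bc$replicates <- NULL
        bc
      }, error = function(e) list(error = conditionMessage(e)))
    }

    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    invisible(report)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
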