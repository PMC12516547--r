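# Nonparametric cumulative incidence (Aalen-Johansen) and Fine-Gray
# subdistribution-hazard regression, implemented from first principles.
# Event coding: 0 = censored, 1 = direct dementia conversion, 2 = first
# confirmed MCI (MCI-only and MCI-to-dementia pooled at first-event time).

#' Build competing-risks data from pathway assignments
#'
#' @param assignments data.frame from [classify_cohort()].
#' @param indices data.frame from [compute_indices()]; its `fdg_z` (and
#'   optionally baseline MMSE/ADAS) become covariates.
#' @param covariates character vector of index columns to carry along
#'   (default `"fdg_z"`).
#' @return data.frame: subject_id, time (years, > 0), event (0/1/2), plus
#'   covariate columns.
#' @export
competing_risks_data <- function(assignments, indices,
                                 covariates = "fdg_z") {
  m <- match(assignments$subject_id, indices$subject_id)
  event <- ifelse(assignments$label == "STABLE", 0L,
           ifelse(assignments$label == "DIRECT_AD", 1L, 2L))
  t_days <- ifelse(event == 0L, assignments$t_censor_days,
                   assignments$t_first_event_days)
  out <- data.frame(subject_id = assignments$subject_id,
                    time = t_days / DAYS_PER_YEAR,
                    event = event, stringsAsFactors = FALSE)
  for (cv in covariates) out[[cv]] <- indices[[cv]][m]
  stopifnot(all(out$time > 0))
  out
}

#' Aalen-Johansen cumulative incidence functions
#'
#' Product-limit estimator under competing risks: `F_k(t) = sum over event
#' times t_i <= t of S(t_i-) d_ki / n_i`, with S the all-cause Kaplan-Meier
#' estimate and ties handled by simultaneous increments.  Variances use the
#' Marubini-Valsecchi (delta-method) estimator.
#'
#' @param time event/censoring times.
#' @param event integer event codes (0 = censored).
#' @return object of class `"cif_estimate"`: list with `time` (sorted unique
#'   event times), `surv` (all-cause KM just after each time), `cif` (matrix,
#'   one column per event type), `var` (same shape), `event_types`.
#' @export
aalen_johansen <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0))
  types <- sort(unique(event[event != 0]))
  if (length(types) == 0) {
    warning("all observations censored: cumulative incidence is zero")
    return(structure(list(time = numeric(0), surv = numeric(0),
                          cif = matrix(0, 0, 0), var = matrix(0, 0, 0),
                          event_types = integer(0)),
                     class = "cif_estimate"))
  }
  ut <- sort(unique(time[event != 0]))
  K <- length(types)
  cif <- matrix(0, length(ut), K, dimnames = list(NULL, paste0("F", types)))
  vmat <- cif
  surv <- numeric(length(ut))
  S <- 1
  # running pieces for the variance estimator
  inc_t <- numeric(0)               # event times with any type-k increment
  inc_Sd <- vector("list", K)       # per-type S(t-) d_k/n at each time
  inc_all <- list(d = numeric(0), n = numeric(0))
  for (i in seq_along(ut)) {
    t0 <- ut[i]
    n_i <- sum(time >= t0)
    d_all <- sum(time == t0 & event != 0)
    Sminus <- S
    for (k in seq_len(K)) {
      d_k <- sum(time == t0 & event == types[k])
      prev <- if (i == 1) 0 else cif[i - 1, k]
      cif[i, k] <- prev + Sminus * d_k / n_i
      inc_Sd[[k]] <- c(inc_Sd[[k]], Sminus * d_k / n_i)
    }
    inc_t <- c(inc_t, t0)
    inc_all$d <- c(inc_all$d, d_all)
    inc_all$n <- c(inc_all$n, n_i)
    S <- S * (1 - d_all / n_i)
    surv[i] <- S
    # Marubini-Valsecchi variance at t0 for each type
    for (k in seq_len(K)) {
      Fk_t <- cif[i, k]
      Fk_ti <- cumsum(inc_Sd[[k]])
      Sm <- c(1, utils::head(cumprod(1 - inc_all$d / inc_all$n), -1))
      d_ki <- inc_Sd[[k]] * inc_all$n / Sm  # recover d_k at each time
      a <- (Fk_t - Fk_ti)^2 * inc_all$d /
        (inc_all$n * pmax(inc_all$n - inc_all$d, 1))
      b <- Sm^2 * ((inc_all$n - d_ki) / inc_all$n) * d_ki / inc_all$n^2
      cc <- (Fk_t - Fk_ti) * Sm * d_ki / inc_all$n^2
      vmat[i, k] <- sum(a) + sum(b) - 2 * sum(cc)
    }
  }
  structure(list(time = ut, surv = surv, cif = cif, var = pmax(vmat, 0),
                 event_types = types),
            class = "cif_estimate")
}

#' Evaluate a cumulative incidence function at given times
#'
#' @param fit a `"cif_estimate"` from [aalen_johansen()].
#' @param times evaluation times.
#' @param type event type (matching `fit$event_types`).
#' @return numeric vector of `F_type(times)` (0 before the first event).
#' @export
cif_at <- function(fit, times, type = 1) {
  k <- match(paste0("F", type), colnames(fit$cif))
  if (is.na(k)) return(rep(0, length(times)))
  idx <- findInterval(times, fit$time)
  ifelse(idx == 0, 0, fit$cif[pmax(idx, 1), k])
}

# Left-continuous Kaplan-Meier of the censoring distribution, evaluated just
# before each requested time: G(t-).
.censoring_km_minus <- function(time, event, at) {
  ct <- sort(unique(time[event == 0]))
  if (!length(ct)) return(rep(1, length(at)))
  G <- cumprod(1 - vapply(ct, function(t0) {
    sum(time == t0 & event == 0) / sum(time >= t0)
  }, numeric(1)))
  idx <- findInterval(at, ct, left.open = TRUE)  # strictly before `at`
  ifelse(idx == 0, 1, G[pmax(idx, 1)])
}

#' Fine-Gray subdistribution-hazard regression
#'
#' Maximizes the subdistribution partial likelihood in which subjects with a
#' competing event remain in the risk set with censoring-survival weight
#' `G(t-)/G(T_j-)` (left-continuous Kaplan-Meier of the censoring times).
#' Newton-Raphson with Breslow tie handling; convergence when the maximum
#' absolute score component falls below `tol_score` or the relative
#' log-likelihood change falls below `tol_ll`.
#'
#' @param time event/censoring times.
#' @param event integer codes (0 = censored).
#' @param X covariate matrix (or vector) with finite entries.
#' @param event_of_interest event code modeled (default 1).
#' @param max_iter,tol_score,tol_ll iteration cap and tolerances.
#' @return object of class `"fine_gray_fit"`: `coef`, `se`, `shr`
#'   (exp(coef)), `vcov`, `loglik`, `score_max`, `iterations`, `converged`,
#'   `separation_flag`.
#' @export
fine_gray_fit <- function(time, event, X, event_of_interest = 1,
                          max_iter = 100, tol_score = 1e-8,
                          tol_ll = 1e-10) {
  X <- as.matrix(X)
  stopifnot(length(time) == nrow(X), length(event) == nrow(X),
            all(is.finite(X)))
  if (sum(event == event_of_interest) < 1) {
    stop("no events of the requested type")
  }
  p <- ncol(X)
  et <- sort(unique(time[event == event_of_interest]))
  Gt <- .censoring_km_minus(time, event, et)        # G(t-) per event time
  GT <- .censoring_km_minus(time, event, time)      # G(T_j-) per subject
  competing <- event != 0 & event != event_of_interest

  # per event time: risk-set membership and weights (n x #times kept sparse
  # via a loop; p is small so this stays cheap)
  beta <- rep(0, p)
  ll_old <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    ex <- exp(eta)
    ll <- 0
    U <- rep(0, p)
    H <- matrix(0, p, p)
    for (m in seq_along(et)) {
      t0 <- et[m]
      at_risk <- time >= t0
      late_competing <- competing & time < t0
      w <- numeric(length(time))
      w[at_risk] <- 1
      w[late_competing] <- Gt[m] / GT[late_competing]
      wex <- w * ex
      S0 <- sum(wex)
      S1 <- drop(crossprod(X, wex))
      S2 <- crossprod(X, X * wex)
      ev <- which(time == t0 & event == event_of_interest)
      d <- length(ev)
      ll <- ll + sum(eta[ev]) - d * log(S0)
      xbar <- S1 / S0
      U <- U + colSums(X[ev, , drop = FALSE]) - d * xbar
      H <- H + d * (S2 / S0 - tcrossprod(xbar))
    }
    trace <- c(trace, ll)
    step <- tryCatch(solve(H, U), error = function(e) {
      stop("singular information matrix in Fine-Gray fit")
    })
    if (max(abs(U)) < tol_score ||
        (is.finite(ll_old) && abs(ll - ll_old) <=
           tol_ll * (abs(ll_old) + 1e-12))) {
      vc <- solve(H)
      return(structure(list(
        coef = beta, se = sqrt(diag(vc)), shr = exp(beta), vcov = vc,
        loglik = ll, score_max = max(abs(U)), iterations = iter,
        converged = TRUE, separation_flag = any(abs(beta) > 15)),
        class = "fine_gray_fit"))
    }
    ll_old <- ll
    beta <- beta + step
  }
  stop("Fine-Gray fit did not converge in ", max_iter,
       " iterations; log-likelihood trace: ",
       paste(sprintf("%.4f", utils::tail(trace, 5)), collapse = ", "))
}

#' @export
print.fine_gray_fit <- function(x, ...) {
  cat("Fine-Gray subdistribution hazard fit\n")
  print(data.frame(coef = x$coef, `exp(coef)` = x$shr, se = x$se,
                   check.names = FALSE))
  invisible(x)
}

#' Subdistribution hazard ratio for a high-vs-low FDG stratum indicator
#'
#' Fits the Fine-Gray model with a single binary covariate (1 = high
#' metabolism stratum, 0 = low) and reports exp(beta) with an optional
#' percentile bootstrap confidence interval over subject resamples.
#'
#' @param time,event as in [fine_gray_fit()].
#' @param high logical: subject in the high-metabolism stratum.
#' @param event_of_interest event code modeled.
#' @param B bootstrap replicates (0 = no CI).
#' @param seed RNG seed for the bootstrap.
#' @return list: `shr`, `coef`, `se`, `ci` (percentile, or Wald when B = 0).
#' @export
sdhr_by_stratum <- function(time, event, high, event_of_interest = 1,
                            B = 0, seed = 1L) {
  keep <- !is.na(high)
  time <- time[keep]; event <- event[keep]; high <- as.numeric(high[keep])
  fit <- fine_gray_fit(time, event, matrix(high, ncol = 1),
                       event_of_interest)
  ci <- exp(fit$coef + c(-1, 1) * stats::qnorm(0.975) * fit$se)
  if (B > 0) {
    set.seed(seed)
    reps <- rep(NA_real_, B)
    n <- length(time)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      reps[b] <- tryCatch(
        fine_gray_fit(time[idx], event[idx],
                      matrix(high[idx], ncol = 1), event_of_interest)$coef,
        error = function(e) NA_real_)
    }
    ci <- exp(stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE,
                              names = FALSE))
  }
  list(shr = unname(fit$shr), coef = unname(fit$coef),
       se = unname(fit$se), ci = ci)
}
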