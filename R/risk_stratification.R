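# Baseline-cognition x FDG decline-risk tables and the decision-framework
# banding built on the 24-month multinomial model.

#' 24-month decline risk by baseline cognition band and FDG level
#'
#' Cognition bands: MMSE 20-23, 24-26, >=27, plus an ADAS >= 30 band
#' (severe impairment; evaluated on ADAS worsening).  Decline is the change
#' from the baseline score to the last available score within the horizon:
#' rapid = >= 3 MMSE points lost, severe = >= 5 MMSE points lost (>= 5 ADAS
#' points gained in the ADAS band).  In a cohort that is cognitively normal
#' at baseline the impaired bands are typically empty; they are reported
#' with n = 0 and missing probabilities rather than forced.
#'
#' @param x a [cohort()] object.
#' @param indices data.frame from [compute_indices()] (supplies tertiles and
#'   baseline scores).
#' @param horizon_days risk horizon (default 730).
#' @return data.frame: band, fdg_level, n, pct_rapid, pct_severe.
#' @export
decline_risk_table <- function(x, indices, horizon_days = 730) {
  vs <- split(x$visits, x$visits$subject_id)
  ids <- indices$subject_id
  delta <- function(id, score) {
    v <- vs[[id]]
    w <- v[v$day <= horizon_days & !is.na(v[[score]]), ]
    if (nrow(w) < 2 || w$day[1] != 0) return(NA_real_)
    w[[score]][1] - w[[score]][nrow(w)]  # positive = points lost
  }
  d_mmse <- vapply(ids, delta, numeric(1), score = "mmse")
  d_adas <- -vapply(ids, delta, numeric(1), score = "adas")  # pos = worse
  mmse0 <- indices$mmse_baseline
  adas0 <- indices$adas_baseline
  bands <- list(
    `MMSE 20-23` = !is.na(mmse0) & mmse0 >= 20 & mmse0 <= 23,
    `MMSE 24-26` = !is.na(mmse0) & mmse0 >= 24 & mmse0 <= 26,
    `MMSE >=27` = !is.na(mmse0) & mmse0 >= 27,
    `ADAS >=30` = !is.na(adas0) & adas0 >= 30)
  rows <- list()
  for (b in names(bands)) {
    adas_band <- b == "ADAS >=30"
    for (lev in c("HIGH", "MID", "LOW")) {
      sel <- bands[[b]] & indices$tertile == lev
      ch <- if (adas_band) d_adas[sel] else d_mmse[sel]
      ch <- ch[!is.na(ch)]
      n <- length(ch)
      rows[[length(rows) + 1L]] <- data.frame(
        band = b, fdg_level = lev, n = n,
        pct_rapid = if (n && !adas_band) 100 * mean(ch >= 3) else NA_real_,
        pct_severe = if (n) 100 * mean(ch >= 5) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' FDG decision bands with model-predicted 24-month pathway probabilities
#'
#' Three bands at the fixed +/-0.5 z cutpoints (interior closed), each
#' carrying the 24-month multinomial model's predicted probability triple at
#' a representative z per band and a fixed monitoring recommendation.
#'
#' @param model a 24-month `"pathway_multinom"` model (FDG-only).
#' @param z_rep representative z per band (defaults -1, 0, +1).
#' @return data.frame: band, z_range, monitoring, plus one percentage
#'   column per outcome class (rows sum to 100).
#' @export
decision_bands <- function(model, z_rep = c(-1, 0, 1)) {
  pr <- predict(model, data.frame(fdg_z = z_rep)) * 100
  out <- data.frame(
    band = c("HIGH_RISK", "INTERMEDIATE", "HIGH_STABILITY"),
    z_range = c("< -0.50", "-0.50 to +0.50", "> +0.50"),
    monitoring = c("every 6-12 months", "every 12-18 months",
                   "every 2-3 years"),
    stringsAsFactors = FALSE)
  for (cl in colnames(pr)) out[[cl]] <- pr[, cl]
  out
}
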