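# Deterministic classification of visit sequences into four progression
# pathways, with 180-day confirmation smoothing, event times and censoring.

PATHWAY_LEVELS <- c("STABLE", "MCI_ONLY", "MCI_TO_AD", "DIRECT_AD")

.dx_severity <- function(dx) match(dx, DIAGNOSIS_LEVELS)  # CN=1 MCI=2 AD=3

#' Confirm diagnostic transitions in a visit sequence
#'
#' A worsened diagnosis at visit i is confirmed iff some later visit at least
#' `min_confirm_days` after it shows the same or a worse diagnosis.  By
#' default a worsening at the final visit, where no lookahead is possible,
#' is accepted as confirmed (`accept_terminal = FALSE` treats terminal
#' worsenings as unconfirmed instead).  Confirmed states ratchet: reversions
#' after a confirmed state never un-confirm it.  Unconfirmed isolated
#' worsenings are ignored and counted as reversions.
#'
#' @param days integer vector of visit days (sorted, first = 0).
#' @param diagnosis character vector over CN/MCI/AD, same length.
#' @param min_confirm_days minimum confirmation interval (default 180; 0
#'   confirms every observed worsening).
#' @param accept_terminal accept a terminal worsening without lookahead
#'   (default TRUE).
#' @return list: `confirmed` (character vector, the ratcheted confirmed state
#'   at each visit), `confirmed_mci_day`, `confirmed_ad_day` (day of the
#'   first visit carrying the later-confirmed diagnosis, or NA), and
#'   `reversion_count` (ignored unconfirmed worsenings).
#' @export
confirm_transitions <- function(days, diagnosis, min_confirm_days = 180,
                                accept_terminal = TRUE) {
  n <- length(days)
  if (n == 0L) stop("empty visit sequence")
  stopifnot(length(diagnosis) == n, !is.unsorted(days, strictly = TRUE))
  sev <- .dx_severity(diagnosis)
  if (anyNA(sev)) stop("unknown diagnosis code")

  confirmed <- integer(n)
  level <- 1L
  reversions <- 0L
  first_day <- c(CN = 0, MCI = NA_real_, AD = NA_real_)
  for (i in seq_len(n)) {
    s <- sev[i]
    if (s > level) {
      later <- which(days - days[i] >= min_confirm_days & seq_len(n) > i)
      ok <- if (min_confirm_days == 0) {
        TRUE  # degenerate setting: every observed worsening is confirmed
      } else if (length(later) && any(sev[later] >= s)) {
        TRUE
      } else {
        # only a terminal worsening may stand without lookahead
        i == n && accept_terminal
      }
      if (ok) {
        if (is.na(first_day[s])) first_day[s] <- days[i]
        level <- s
      } else {
        reversions <- reversions + 1L
      }
    }
    confirmed[i] <- level
  }
  list(confirmed = DIAGNOSIS_LEVELS[confirmed],
       confirmed_mci_day = unname(first_day["MCI"]),
       confirmed_ad_day = unname(first_day["AD"]),
       reversion_count = reversions)
}

#' Classify one subject's confirmed sequence into a progression pathway
#'
#' STABLE: no confirmed worsening (censored at last visit).  MCI_ONLY:
#' confirmed MCI, never confirmed dementia.  MCI_TO_AD: confirmed MCI then
#' confirmed dementia.  DIRECT_AD: confirmed dementia with no confirmed MCI
#' at any visit (a single unconfirmed MCI visit before dementia still yields
#' DIRECT_AD — unconfirmed diagnoses are fluctuation).
#'
#' @param subject_id subject identifier.
#' @param days,diagnosis visit days and diagnoses (as in
#'   [confirm_transitions()]).
#' @inheritParams confirm_transitions
#' @return one-row data.frame: subject_id, label, t_first_event_days,
#'   t_censor_days, confirmed_mci_day, confirmed_ad_day, reversion_count.
#' @export
classify_subject <- function(subject_id, days, diagnosis,
                             min_confirm_days = 180, accept_terminal = TRUE) {
  cf <- confirm_transitions(days, diagnosis, min_confirm_days,
                            accept_terminal)
  mci <- cf$confirmed_mci_day
  ad <- cf$confirmed_ad_day
  label <- if (is.na(mci) && is.na(ad)) "STABLE"
  else if (!is.na(mci) && is.na(ad)) "MCI_ONLY"
  else if (!is.na(mci)) "MCI_TO_AD"
  else "DIRECT_AD"
  t_event <- if (label == "STABLE") NA_real_ else min(mci, ad, na.rm = TRUE)
  data.frame(subject_id = subject_id, label = label,
             t_first_event_days = t_event,
             t_censor_days = max(days),
             confirmed_mci_day = mci, confirmed_ad_day = ad,
             reversion_count = cf$reversion_count,
             stringsAsFactors = FALSE)
}

#' Classify every subject in a cohort
#'
#' @param x a [cohort()] object (normally the output of
#'   [eligibility_filter()]).
#' @inheritParams confirm_transitions
#' @return data.frame of pathway assignments, one row per subject (see
#'   [classify_subject()]).
#' @export
classify_cohort <- function(x, min_confirm_days = 180,
                            accept_terminal = TRUE) {
  stopifnot(inherits(x, "cohort"))
  vs <- split(x$visits, x$visits$subject_id)
  out <- lapply(x$subjects$subject_id, function(id) {
    v <- vs[[id]]
    classify_subject(id, v$day, v$diagnosis, min_confirm_days,
                     accept_terminal)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-pathway summary with the metabolic gradient statistics
#'
#' Summarizes N, percent, FDG z (mean, SD), cognitive reserve and
#' vulnerability index by pathway, plus two gradient statistics: the FDG
#' difference between the stable and direct-conversion pathways and between
#' the MCI-only and direct pathways (pathway switching gap), both in cohort
#' SD units.  Pathways with no subjects report NA statistics, not zero.
#'
#' @param assignments data.frame from [classify_cohort()].
#' @param fdg_z named numeric vector of FDG z-scores (names = subject_id).
#' @param reserve optional named numeric vector of cognitive reserve.
#' @param vulnerability optional named numeric vector of vulnerability index.
#' @return list: `table` (per-pathway data.frame), `gradient_sd`
#'   (stable - direct FDG), `switching_gap_sd` (MCI-only - direct FDG).
#' @export
pathway_summary <- function(assignments, fdg_z, reserve = NULL,
                            vulnerability = NULL) {
  z <- fdg_z[assignments$subject_id]
  grp <- factor(assignments$label, levels = PATHWAY_LEVELS)
  stat <- function(v, f) {
    vapply(levels(grp), function(g) {
      vals <- v[grp == g & !is.na(v)]
      if (length(vals)) f(vals) else NA_real_
    }, numeric(1))
  }
  n <- as.integer(table(grp))
  tab <- data.frame(
    pathway = PATHWAY_LEVELS,
    n = n,
    pct = 100 * n / length(grp),
    fdg_mean = stat(z, mean),
    fdg_sd = stat(z, stats::sd),
    reserve_mean = if (is.null(reserve)) NA_real_
      else stat(reserve[assignments$subject_id], mean),
    vulnerability_mean = if (is.null(vulnerability)) NA_real_
      else stat(vulnerability[assignments$subject_id], mean),
    stringsAsFactors = FALSE)
  list(table = tab,
       gradient_sd = tab$fdg_mean[1] - tab$fdg_mean[4],
       switching_gap_sd = tab$fdg_mean[2] - tab$fdg_mean[4])
}

#' Write pathway assignments to CSV
#'
#' @param assignments data.frame from [classify_cohort()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.csv(assignments, path, row.names = FALSE, na = "")
  invisible(path)
}
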