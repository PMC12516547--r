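# FDG-stratified discrete-time (annual) transition matrices over CN/MCI/AD
# and geometric sojourn times.

#' Sample a subject's confirmed state at each anniversary
#'
#' Builds the annual state sequence the Markov estimator consumes: the state
#' at anniversary k*cycle_days is the last confirmed (ratcheted) state at or
#' before that day, using last observation carried forward between visits.
#' The sequence ends at the last complete cycle within follow-up; a subject
#' with no complete cycle contributes nothing.
#'
#' @param days visit days (sorted, first = 0).
#' @param confirmed confirmed diagnosis per visit (from
#'   [confirm_transitions()]).
#' @param cycle_days cycle length (default 365).
#' @return character vector of states at anniversaries 0, 1, 2, ... (length
#'   `floor(last_day/cycle_days) + 1`), or a zero-length vector when no
#'   complete cycle exists.
#' @export
annualize_states <- function(days, confirmed, cycle_days = 365) {
  stopifnot(length(days) == length(confirmed))
  k_max <- floor(max(days) / cycle_days)
  if (k_max < 1) return(character(0))
  anniversaries <- (0:k_max) * cycle_days
  idx <- findInterval(anniversaries, days)
  sev <- cummax(.dx_severity(confirmed))  # ratchet (already monotone)
  DIAGNOSIS_LEVELS[sev[idx]]
}

#' Estimate annual transition matrices per FDG stratum
#'
#' Maximum-likelihood estimates `p_ij = n_ij / sum_j n_ij` from the pooled
#' one-cycle transitions of all subjects in each stratum.  The AD row is
#' fixed at (0, 0, 1) (absorbing); a CN or MCI row with zero exposure is
#' reported as missing.
#'
#' @param state_sequences list of annual state sequences (from
#'   [annualize_states()]).
#' @param strata factor/character of stratum labels, one per sequence.
#' @return named list of per-stratum lists with elements `P` (3x3 matrix),
#'   `counts` (3x3 transition counts), `exposure` (row totals).
#' @export
estimate_transition_matrix <- function(state_sequences, strata) {
  stopifnot(length(state_sequences) == length(strata))
  strata <- as.character(strata)
  out <- list()
  for (g in unique(strata[!is.na(strata)])) {
    counts <- matrix(0, 3, 3,
                     dimnames = list(DIAGNOSIS_LEVELS, DIAGNOSIS_LEVELS))
    for (sq in state_sequences[which(strata == g)]) {
      if (length(sq) < 2) next
      from <- .dx_severity(sq[-length(sq)])
      to <- .dx_severity(sq[-1])
      for (t in seq_along(from)) {
        counts[from[t], to[t]] <- counts[from[t], to[t]] + 1
      }
    }
    if (sum(counts) == 0) stop("no observed transitions in stratum ", g)
    exposure <- rowSums(counts)
    P <- counts / ifelse(exposure > 0, exposure, NA)
    P["AD", ] <- c(0, 0, 1)  # absorbing by construction
    out[[g]] <- list(P = P, counts = counts, exposure = exposure)
  }
  out
}

#' Expected sojourn time of a discrete-time state
#'
#' Mean number of annual cycles spent in a state with self-transition
#' probability `p_stay`: `1/(1 - p_stay)` (geometric duration; at least one
#' cycle).  `p_stay = 1` gives `Inf`.
#'
#' @param p_stay self-transition probability in `[0, 1]`.
#' @return expected years in state.
#' @export
sojourn_time <- function(p_stay) {
  stopifnot(all(p_stay >= 0 & p_stay <= 1, na.rm = TRUE))
  ifelse(p_stay == 1, Inf, 1 / (1 - p_stay))
}

#' Sojourn table for stratified transition matrices
#'
#' @param matrices named list from [estimate_transition_matrix()].
#' @return data.frame: stratum, sojourn_cn, sojourn_mci (years).
#' @export
sojourn_table <- function(matrices) {
  data.frame(
    stratum = names(matrices),
    sojourn_cn = vapply(matrices,
                        function(m) sojourn_time(m$P["CN", "CN"]),
                        numeric(1)),
    sojourn_mci = vapply(matrices,
                         function(m) sojourn_time(m$P["MCI", "MCI"]),
                         numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Metabolic-effect contrasts between transition matrices
#'
#' Per-transition difference (low-metabolism stratum minus high), in
#' percentage points, plus the CN sojourn advantage (high minus low, years).
#'
#' @param matrices named list from [estimate_transition_matrix()].
#' @param low,high stratum names to contrast (defaults "LOW", "HIGH").
#' @return list: `delta_pp` (3x3 matrix of (low - high) x 100),
#'   `sojourn_advantage_cn`, `sojourn_advantage_mci` (years).
#' @export
matrix_contrasts <- function(matrices, low = "LOW", high = "HIGH") {
  stopifnot(all(c(low, high) %in% names(matrices)))
  Pl <- matrices[[low]]$P
  Ph <- matrices[[high]]$P
  list(delta_pp = (Pl - Ph) * 100,
       sojourn_advantage_cn = sojourn_time(Ph["CN", "CN"]) -
         sojourn_time(Pl["CN", "CN"]),
       sojourn_advantage_mci = sojourn_time(Ph["MCI", "MCI"]) -
         sojourn_time(Pl["MCI", "MCI"]))
}

#' Full Markov analysis of a classified cohort
#'
#' Confirms each subject's sequence, annualizes it, and estimates per-tertile
#' transition matrices with sojourn times and low-vs-high contrasts.
#'
#' @param x an eligible [cohort()].
#' @param indices data.frame from [compute_indices()] (supplies tertiles).
#' @param cycle_days annual cycle length.
#' @param min_confirm_days confirmation interval passed to
#'   [confirm_transitions()].
#' @return list: `matrices`, `sojourns`, `contrasts`.
#' @export
markov_analysis <- function(x, indices, cycle_days = 365,
                            min_confirm_days = 180) {
  vs <- split(x$visits, x$visits$subject_id)
  seqs <- lapply(x$subjects$subject_id, function(id) {
    v <- vs[[id]]
    cf <- confirm_transitions(v$day, v$diagnosis, min_confirm_days)
    annualize_states(v$day, cf$confirmed, cycle_days)
  })
  strata <- indices$tertile[match(x$subjects$subject_id,
                                  indices$subject_id)]
  mats <- estimate_transition_matrix(seqs, strata)
  list(matrices = mats,
       sojourns = sojourn_table(mats),
       contrasts = if (all(c("LOW", "HIGH") %in% names(mats))) {
         matrix_contrasts(mats)
       } else NULL)
}
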