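# ROC construction and Youden-optimal FDG z cutpoints for the three decision
# contrasts, plus dose-response binning.  Risk direction is fixed once: lower
# FDG means higher risk, so scores entering the ROC are negated z values.

#' Empirical ROC curve
#'
#' Sensitivity and specificity at every distinct score cutpoint (predict
#' positive when `score >= threshold`), with trapezoidal AUC (equal to the
#' Mann-Whitney rank statistic).
#'
#' @param score numeric risk scores (higher = more likely positive).
#' @param label logical/0-1 class labels.
#' @return object of class `"roc_curve"`: `threshold`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
roc_curve <- function(score, label) {
  ok <- !is.na(score) & !is.na(label)
  score <- score[ok]; label <- as.logical(label[ok])
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) stop("both classes required for a ROC curve")
  thr <- sort(unique(score), decreasing = TRUE)
  sens <- vapply(thr, function(t0) sum(score >= t0 & label) / n1, numeric(1))
  spec <- vapply(thr, function(t0) sum(score < t0 & !label) / n0, numeric(1))
  fpr <- c(0, 1 - spec, 1)
  tpr <- c(0, sens, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(threshold = thr, sensitivity = sens, specificity = spec,
                 auc = auc, score_median = stats::median(score)),
            class = "roc_curve")
}

#' Youden-optimal cutpoint of a ROC curve
#'
#' Maximizes `J = sensitivity + specificity - 1`; ties are broken toward the
#' cutpoint nearest the score median.
#'
#' @param roc a `"roc_curve"` object.
#' @return list: `threshold`, `youden_j`, `sensitivity`, `specificity`.
#' @export
youden_optimal <- function(roc) {
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j == max(j))
  if (length(best) > 1) {
    best <- best[which.min(abs(roc$threshold[best] - roc$score_median))]
  }
  list(threshold = roc$threshold[best],
       youden_j = j[best],
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best])
}

#' Youden cutpoints for the three pathway decision contrasts
#'
#' Contrasts: (a) stability vs any decline, (b) sequential decline (MCI-only
#' or MCI-to-dementia) vs direct conversion among decliners, (c) direct
#' conversion vs all others.  All contrasts share the fixed risk direction
#' (lower FDG = higher risk); cutpoints are reported on the FDG z scale.
#'
#' @param assignments data.frame from [classify_cohort()].
#' @param fdg_z named numeric vector of z-scores (names = subject_id).
#' @return data.frame: contrast, cutpoint_z, youden_j, sensitivity,
#'   specificity, auc, n_pos, n_neg.  A contrast with an empty arm is
#'   reported with NA statistics.
#' @export
contrast_suite <- function(assignments, fdg_z) {
  z <- fdg_z[assignments$subject_id]
  lab <- assignments$label
  defs <- list(
    stability_vs_decline = list(pos = lab != "STABLE", keep = TRUE),
    sequential_vs_direct = list(pos = lab == "DIRECT_AD",
                                keep = lab != "STABLE"),
    direct_vs_rest = list(pos = lab == "DIRECT_AD", keep = TRUE))
  rows <- lapply(names(defs), function(nm) {
    d <- defs[[nm]]
    keep <- if (isTRUE(d$keep)) rep(TRUE, length(lab)) else d$keep
    pos <- d$pos[keep]
    zz <- z[keep]
    if (sum(pos, na.rm = TRUE) == 0 || sum(!pos, na.rm = TRUE) == 0) {
      return(data.frame(contrast = nm, cutpoint_z = NA_real_,
                        youden_j = NA_real_, sensitivity = NA_real_,
                        specificity = NA_real_, auc = NA_real_,
                        n_pos = sum(pos, na.rm = TRUE),
                        n_neg = sum(!pos, na.rm = TRUE),
                        stringsAsFactors = FALSE))
    }
    roc <- roc_curve(-zz, pos)  # lower metabolism = higher risk
    yo <- youden_optimal(roc)
    data.frame(contrast = nm, cutpoint_z = -yo$threshold,
               youden_j = yo$youden_j, sensitivity = yo$sensitivity,
               specificity = yo$specificity, auc = roc$auc,
               n_pos = sum(pos), n_neg = sum(!pos),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Dose-response outcome profile across FDG z bins
#'
#' @param fdg_z named numeric z-scores (names = subject_id).
#' @param assignments data.frame from [classify_cohort()].
#' @param bin_edges strictly increasing interior edges; defaults
#'   `c(-2, -1, -0.5, 0, 0.5, 1, 2)` (with open outer bins).
#' @return data.frame per bin: bin, n, pct_direct_ad, pct_stable,
#'   pct_mci_only, pct_mci_to_ad (percentages within bin; empty bins keep
#'   n = 0 and NA percentages).
#' @export
dose_response_bins <- function(fdg_z, assignments,
                               bin_edges = c(-2, -1, -0.5, 0, 0.5, 1, 2)) {
  stopifnot(!is.unsorted(bin_edges, strictly = TRUE))
  z <- fdg_z[assignments$subject_id]
  br <- c(-Inf, bin_edges, Inf)
  bin <- cut(z, breaks = br)
  lev <- levels(bin)
  rows <- lapply(lev, function(b) {
    idx <- which(bin == b)
    n <- length(idx)
    pct <- function(l) if (n) 100 * mean(assignments$label[idx] == l)
      else NA_real_
    data.frame(bin = b, n = n,
               pct_stable = pct("STABLE"), pct_mci_only = pct("MCI_ONLY"),
               pct_mci_to_ad = pct("MCI_TO_AD"),
               pct_direct_ad = pct("DIRECT_AD"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
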