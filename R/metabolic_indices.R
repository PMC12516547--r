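# FDG standardization and stratification, composite cognitive/metabolic
# indices, amyloid mixture-model positivity, PCA atrophy index, and composite
# vulnerability.

#' Standardize raw FDG MetaROI values to cohort z-scores
#'
#' `(x - mean)/SD` over non-missing values; missing propagates.  Sample SD
#' (n-1 denominator) by default, switchable to the population SD.
#'
#' @param fdg_raw numeric vector of raw MetaROI values.
#' @param type `"sample"` (default) or `"population"` SD.
#' @return numeric vector of z-scores (mean 0, SD 1 over non-missing input).
#' @export
fdg_zscore <- function(fdg_raw, type = c("sample", "population")) {
  type <- match.arg(type)
  v <- fdg_raw[!is.na(fdg_raw)]
  if (length(v) < 2) stop("need >= 2 non-missing FDG values")
  s <- stats::sd(v)
  if (type == "population") s <- s * sqrt((length(v) - 1) / length(v))
  if (s == 0) stop("zero variance in FDG values")
  (fdg_raw - mean(v)) / s
}

#' Stratify FDG z-scores into tertiles and fixed risk categories
#'
#' Tertile boundaries sit at the empirical 1/3 and 2/3 quantiles (LOW = most
#' hypometabolic third).  Categories use fixed cutpoints: HIGH_RISK below
#' -0.5, INTERMEDIATE on the closed interval [-0.5, +0.5], HIGH_STABILITY
#' above +0.5 (boundary ties go to the middle band).
#'
#' @param fdg_z numeric vector of z-scores.
#' @return data.frame with columns `fdg_z`, `tertile` (factor LOW/MID/HIGH)
#'   and `category` (factor HIGH_RISK/INTERMEDIATE/HIGH_STABILITY).
#' @export
fdg_strata <- function(fdg_z) {
  q <- stats::quantile(fdg_z, c(1, 2) / 3, na.rm = TRUE, names = FALSE,
                       type = 7)
  tertile <- cut(fdg_z, c(-Inf, q, Inf), labels = c("LOW", "MID", "HIGH"),
                 right = TRUE)
  category <- factor(ifelse(fdg_z < -0.5, "HIGH_RISK",
                     ifelse(fdg_z > 0.5, "HIGH_STABILITY", "INTERMEDIATE")),
                     levels = c("HIGH_RISK", "INTERMEDIATE",
                                "HIGH_STABILITY"))
  data.frame(fdg_z = fdg_z, tertile = tertile, category = category)
}

#' Cognitive reserve composite: MMSE - ADAS/3
#'
#' @param mmse,adas numeric vectors; missing input gives missing output.
#' @return numeric vector (points, at most 30).
#' @export
cognitive_reserve <- function(mmse, adas) mmse - adas / 3

#' Metabolic-cognitive vulnerability index
#'
#' Interaction score `max(0, 1 - fdg_z) * max(0, 30 - reserve) / 4`, a
#' package-defined composite that is zero when both metabolism and reserve
#' are fully protective and monotone increasing in hypometabolism and in
#' reserve depletion.
#'
#' @param fdg_z FDG z-score.
#' @param reserve cognitive reserve from [cognitive_reserve()].
#' @return non-negative numeric vector.
#' @export
vulnerability_index <- function(fdg_z, reserve) {
  pmax(0, -fdg_z + 1) * pmax(0, 30 - reserve) / 4
}

#' Amyloid positivity from a two-component Gaussian mixture
#'
#' Fits a univariate 2-component Gaussian mixture to centiloid values by EM
#' with deterministic initialization (split at the median), and calls a
#' subject positive when the posterior probability of the higher-mean
#' component is at least 0.5.  A fit where either component weight collapses
#' below 0.02 is flagged degenerate.
#'
#' @param centiloid numeric vector (>= 20 non-missing values required).
#' @param max_iter,tol EM iteration cap (2000; overlapping or collapsing
#'   components approach the likelihood plateau slowly) and log-likelihood
#'   convergence tolerance.
#' @return list: `posterior_positive`, `positive` (per input value, NA where
#'   input missing), `weights`, `means`, `sds` (positive component second),
#'   `loglik`, `iterations`, `degenerate`.
#' @export
amyloid_positivity <- function(centiloid, max_iter = 2000, tol = 1e-8) {
  x <- centiloid[!is.na(centiloid)]
  if (length(x) < 20) stop("need >= 20 non-missing centiloid values")
  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  mu <- c(mean(lo), mean(hi))
  sg <- pmax(c(stats::sd(lo), stats::sd(hi)), 1e-3)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r2 <- d2 / tot
    if (abs(ll - ll_old) < tol) break
    if (it >= max_iter) {
      stop(sprintf(
        "EM did not converge in %d iterations (last delta %.3g)",
        max_iter, abs(ll - ll_old)))
    }
    ll_old <- ll
    n2 <- sum(r2); n1 <- length(x) - n2
    w <- c(n1, n2) / length(x)
    mu <- c(sum((1 - r2) * x) / n1, sum(r2 * x) / n2)
    sg <- pmax(sqrt(c(sum((1 - r2) * (x - mu[1])^2) / n1,
                      sum(r2 * (x - mu[2])^2) / n2)), 1e-6)
  }
  # orient so the positive component is the higher mean
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sg <- rev(sg); w <- rev(w); r2 <- 1 - r2
  }
  post <- rep(NA_real_, length(centiloid))
  post[!is.na(centiloid)] <- r2
  list(posterior_positive = post,
       positive = post >= 0.5,
       weights = w, means = mu, sds = sg,
       loglik = ll, iterations = it,
       degenerate = any(w < 0.02))
}

#' PCA-based structural atrophy index
#'
#' Runs principal component analysis on the standardized triple (hippocampal
#' volume, whole-brain volume, hippocampus/brain ratio); the first component
#' score is z-scored and sign-oriented so that higher = worse (negative
#' loading on hippocampal volume).
#'
#' @param hippocampus_vol,brain_vol numeric vectors (mm^3); rows with a
#'   missing value get a missing index.
#' @return list: `atrophy_index_z` (cohort mean 0, SD 1 over complete
#'   pairs), `ratio` (hippocampus/brain), `loadings` (first-PC loadings).
#' @export
atrophy_index <- function(hippocampus_vol, brain_vol) {
  ratio <- hippocampus_vol / brain_vol
  m <- cbind(hippocampus_vol, brain_vol, ratio)
  ok <- stats::complete.cases(m)
  if (sum(ok) < 2) stop("need >= 2 complete volume pairs")
  if (any(apply(m[ok, , drop = FALSE], 2, stats::sd) == 0)) {
    stop("constant column in atrophy inputs")
  }
  pc <- stats::prcomp(m[ok, , drop = FALSE], center = TRUE, scale. = TRUE)
  score <- pc$x[, 1]
  load1 <- pc$rotation[, 1]
  if (load1["hippocampus_vol"] > 0) {  # orient: higher index = worse
    score <- -score
    load1 <- -load1
  }
  z <- rep(NA_real_, length(hippocampus_vol))
  z[ok] <- (score - mean(score)) / stats::sd(score)
  list(atrophy_index_z = z, ratio = ratio, loadings = load1)
}

#' Composite vulnerability: z(centiloid) + z(atrophy index)
#'
#' @param centiloid numeric vector.
#' @param atrophy_index_z atrophy index from [atrophy_index()].
#' @return numeric vector (sum of the two z-scores; symmetric in its
#'   standardized inputs).
#' @export
composite_vulnerability <- function(centiloid, atrophy_index_z) {
  cz <- (centiloid - mean(centiloid, na.rm = TRUE)) /
    stats::sd(centiloid, na.rm = TRUE)
  az <- (atrophy_index_z - mean(atrophy_index_z, na.rm = TRUE)) /
    stats::sd(atrophy_index_z, na.rm = TRUE)
  cz + az
}

#' Amyloid positivity profile across composite-vulnerability deciles
#'
#' Bins the composite vulnerability index into deciles and reports percent
#' amyloid-positive per bin plus a monotonicity statistic (Spearman
#' correlation of bin index with positivity rate).  With fewer than 10
#' complete subjects, falls back to a single bin with a warning.
#'
#' @param composite composite vulnerability values.
#' @param positive logical amyloid calls.
#' @return list: `table` (decile, n, pct_positive), `spearman`.
#' @export
vulnerability_deciles <- function(composite, positive) {
  ok <- !is.na(composite) & !is.na(positive)
  x <- composite[ok]; y <- positive[ok]
  if (length(x) < 10) {
    warning("fewer than 10 subjects: single-bin fallback")
    tab <- data.frame(decile = 1L, n = length(x),
                      pct_positive = 100 * mean(y))
    return(list(table = tab, spearman = NA_real_))
  }
  dec <- cut(rank(x, ties.method = "first"),
             breaks = seq(0, length(x), length.out = 11), labels = FALSE)
  pct <- vapply(1:10, function(d) 100 * mean(y[dec == d]), numeric(1))
  n <- vapply(1:10, function(d) sum(dec == d), integer(1))
  tab <- data.frame(decile = 1:10, n = n, pct_positive = pct)
  list(table = tab,
       spearman = suppressWarnings(
         stats::cor(1:10, pct, method = "spearman")))
}

#' Odds ratio of amyloid positivity, high vs low atrophy tertile
#'
#' 2x2 odds ratio with a Woolf logit 95% confidence interval; zero cells get
#' the Haldane-Anscombe 0.5 correction (flagged).
#'
#' @param positive logical amyloid calls.
#' @param tertile factor with levels LOW/MID/HIGH (atrophy tertiles).
#' @return list: `or`, `ci` (length 2), `table` (2x2 counts),
#'   `corrected` (logical).
#' @export
positivity_or_by_atrophy_tertile <- function(positive, tertile) {
  ok <- !is.na(positive) & !is.na(tertile)
  positive <- positive[ok]; tertile <- tertile[ok]
  hi <- tertile == "HIGH"; lo <- tertile == "LOW"
  if (!any(hi) || !any(lo)) stop("empty tertile group")
  tab <- matrix(c(sum(hi & positive), sum(hi & !positive),
                  sum(lo & positive), sum(lo & !positive)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("HIGH", "LOW"),
                                c("positive", "negative")))
  corrected <- any(tab == 0)
  t2 <- if (corrected) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  se <- sqrt(sum(1 / t2))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  list(or = or, ci = ci, table = tab, corrected = corrected)
}

#' Per-subject index table for a cohort
#'
#' Convenience wrapper computing every baseline index the downstream modules
#' consume: FDG z-score, tertile and category, cognitive reserve (from the
#' baseline visit), vulnerability index, centiloid z, amyloid call, atrophy
#' index and composite vulnerability.
#'
#' @param x a [cohort()] object (eligible subjects).
#' @param gmm_min_n minimum non-missing centiloids to attempt the amyloid
#'   mixture fit (otherwise amyloid columns are NA).
#' @return data.frame keyed by subject_id.
#' @export
compute_indices <- function(x, gmm_min_n = 20) {
  stopifnot(inherits(x, "cohort"))
  s <- x$subjects
  z <- fdg_zscore(s$fdg_raw)
  strat <- fdg_strata(z)
  base <- x$visits[x$visits$day == 0, ]
  base <- base[match(s$subject_id, base$subject_id), ]
  reserve <- cognitive_reserve(base$mmse, base$adas)
  vuln <- vulnerability_index(z, reserve)
  amy_pos <- rep(NA, nrow(s))
  amy_post <- rep(NA_real_, nrow(s))
  if (sum(!is.na(s$centiloid)) >= gmm_min_n) {
    am <- tryCatch(amyloid_positivity(s$centiloid), error = function(e) {
      warning("amyloid mixture fit failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(am)) {
      amy_pos <- am$positive
      amy_post <- am$posterior_positive
    }
  }
  atr <- tryCatch(atrophy_index(s$hippocampus_vol, s$brain_vol),
                  error = function(e) list(atrophy_index_z =
                                             rep(NA_real_, nrow(s))))
  comp <- if (all(is.na(atr$atrophy_index_z)) || all(is.na(s$centiloid))) {
    rep(NA_real_, nrow(s))
  } else {
    composite_vulnerability(s$centiloid, atr$atrophy_index_z)
  }
  data.frame(subject_id = s$subject_id,
             fdg_z = z, tertile = strat$tertile, category = strat$category,
             mmse_baseline = base$mmse, adas_baseline = base$adas,
             cognitive_reserve = reserve, vulnerability_index = vuln,
             amyloid_posterior = amy_post, amyloid_positive = amy_pos,
             atrophy_index_z = atr$atrophy_index_z,
             composite_vulnerability = comp,
             stringsAsFactors = FALSE)
}
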