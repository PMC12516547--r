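# Horizon-specific multinomial pathway prediction from baseline FDG
# (optionally plus cognition), with discrimination, calibration, and
# leakage-safe cross-validation.

HORIZON_CLASSES <- c("STABLE", "MCI_FIRST", "DIRECT_AD")

#' Build horizon-specific pathway outcomes
#'
#' Labels each subject at a prediction horizon: DIRECT_AD if dementia was
#' confirmed by the horizon with no prior confirmed MCI, MCI_FIRST if MCI
#' was the first confirmed event by the horizon, STABLE if followed (or
#' event-free) past the horizon.  Subjects censored before the horizon with
#' no event have unknown outcome and are excluded from that horizon's fit.
#'
#' @param assignments data.frame from [classify_cohort()].
#' @param horizon_months horizon in months (12, 24 or 36 in the usual runs).
#' @return data.frame: subject_id, horizon_months, label (factor over
#'   STABLE/MCI_FIRST/DIRECT_AD), known (logical).
#' @export
build_horizon_outcomes <- function(assignments, horizon_months) {
  H <- horizon_months * DAYS_PER_YEAR / 12
  ev <- assignments$t_first_event_days
  label <- rep(NA_character_, nrow(assignments))
  known <- rep(FALSE, nrow(assignments))
  has_event_by_H <- !is.na(ev) & ev <= H
  label[has_event_by_H] <- ifelse(
    assignments$label[has_event_by_H] == "DIRECT_AD",
    "DIRECT_AD", "MCI_FIRST")
  known[has_event_by_H] <- TRUE
  event_after <- !is.na(ev) & ev > H
  followed_past <- is.na(ev) & assignments$t_censor_days >= H
  label[event_after | followed_past] <- "STABLE"
  known[event_after | followed_past] <- TRUE
  data.frame(subject_id = assignments$subject_id,
             horizon_months = horizon_months,
             label = factor(label, levels = HORIZON_CLASSES),
             known = known, stringsAsFactors = FALSE)
}

#' Fit a multinomial pathway model
#'
#' Maximum-likelihood softmax regression with STABLE as the reference class
#' (fitted through `nnet::multinom` with tight convergence settings, plus an
#' optional small L2 ridge via its weight decay for separation-prone
#' designs).
#'
#' @param outcomes data.frame from [build_horizon_outcomes()] (only rows
#'   with `known = TRUE` are used).
#' @param predictors data.frame of predictor columns keyed by `subject_id`
#'   (e.g. from [compute_indices()]).
#' @param predictor_cols columns of `predictors` to use (default `"fdg_z"`).
#' @param ridge L2 penalty (weight decay); 0 for plain maximum likelihood.
#' @return object of class `"pathway_multinom"`: `fit` (the multinom
#'   object), `predictor_cols`, `classes`.
#' @export
fit_multinomial <- function(outcomes, predictors,
                            predictor_cols = "fdg_z", ridge = 0) {
  d <- outcomes[outcomes$known, c("subject_id", "label")]
  m <- match(d$subject_id, predictors$subject_id)
  for (pc in predictor_cols) d[[pc]] <- predictors[[pc]][m]
  d <- d[stats::complete.cases(d), ]
  if (length(unique(d$label[!is.na(d$label)])) < 2) {
    stop("need >= 2 observed outcome classes")
  }
  d$label <- droplevels(d$label)
  f <- stats::as.formula(paste("label ~",
                               paste(predictor_cols, collapse = " + ")))
  fit <- nnet::multinom(f, data = d, trace = FALSE, decay = ridge,
                        maxit = 500, reltol = 1e-14)
  structure(list(fit = fit, predictor_cols = predictor_cols,
                 classes = levels(d$label), data = d),
            class = "pathway_multinom")
}

#' Predicted class probabilities
#'
#' @param object a `"pathway_multinom"` model.
#' @param newdata data.frame with the predictor columns.
#' @param ... unused.
#' @return matrix of probabilities, one column per class (rows sum to 1).
#' @export
predict.pathway_multinom <- function(object, newdata, ...) {
  pr <- stats::predict(object$fit, newdata = newdata, type = "probs")
  if (is.null(dim(pr))) {
    if (length(object$classes) == 2) {
      # binary reduction: multinom returns P(second class) as a vector
      pr <- cbind(1 - pr, pr)
      colnames(pr) <- object$classes
    } else {
      # single-row newdata: multinom returns a named probability vector
      pr <- matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
    }
  }
  pr
}

#' One-vs-rest AUC by the rank statistic
#'
#' Mann-Whitney formulation with half credit for ties.
#'
#' @param score predicted probability (or any monotone score) for the
#'   positive class.
#' @param positive logical vector.
#' @return AUC in `[0, 1]`, or NA when a class is absent.
#' @export
auc_rank <- function(score, positive) {
  ok <- !is.na(score) & !is.na(positive)
  score <- score[ok]; positive <- positive[ok]
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hosmer-Lemeshow statistic over probability deciles
#'
#' Bins by deciles of predicted probability, merging bins until every bin's
#' expected count (positives and negatives) is at least `min_expected`.
#'
#' @param prob predicted probabilities.
#' @param y observed 0/1 outcomes.
#' @param bins initial number of bins (default 10).
#' @param min_expected minimum expected count per bin (default 5).
#' @return list: `statistic`, `df`, `p_value`, `table`.
#' @export
hosmer_lemeshow <- function(prob, y, bins = 10, min_expected = 5) {
  ok <- !is.na(prob) & !is.na(y)
  prob <- prob[ok]; y <- as.numeric(y[ok])
  br <- unique(stats::quantile(prob, seq(0, 1, length.out = bins + 1)))
  g <- cut(prob, breaks = br, include.lowest = TRUE, labels = FALSE)
  agg <- function(g) {
    data.frame(n = as.vector(table(g)),
               obs = tapply(y, g, sum),
               exp = tapply(prob, g, sum))
  }
  tab <- agg(g)
  # merge small bins upward
  while (nrow(tab) > 1 &&
         any(pmin(tab$exp, tab$n - tab$exp) < min_expected)) {
    i <- which.min(pmin(tab$exp, tab$n - tab$exp))
    j <- if (i == nrow(tab)) i - 1 else i + 1
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$obs[j] <- tab$obs[j] + tab$obs[i]
    tab$exp[j] <- tab$exp[j] + tab$exp[i]
    tab <- tab[-i, ]
  }
  expn <- tab$exp
  stat <- sum((tab$obs - expn)^2 / (expn * (1 - expn / tab$n)))
  df <- max(nrow(tab) - 2, 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       table = tab)
}

#' Discrimination and calibration report for a fitted pathway model
#'
#' Per-class one-vs-rest AUC (rank statistic, ties get half credit), Brier
#' score (mean squared probability-indicator difference), and
#' Hosmer-Lemeshow calibration.
#'
#' @param model a `"pathway_multinom"` model.
#' @param outcomes data.frame from [build_horizon_outcomes()].
#' @param predictors predictor table keyed by subject_id.
#' @return data.frame: class, n, events, auc, brier, hl_stat, hl_p.
#' @export
evaluate_predictions <- function(model, outcomes, predictors) {
  d <- outcomes[outcomes$known, c("subject_id", "label")]
  m <- match(d$subject_id, predictors$subject_id)
  for (pc in model$predictor_cols) d[[pc]] <- predictors[[pc]][m]
  d <- d[stats::complete.cases(d), ]
  pr <- predict(model, d)
  rows <- lapply(model$classes, function(cl) {
    y <- d$label == cl
    if (!any(y) || all(y)) {
      return(data.frame(class = cl, n = nrow(d), events = sum(y),
                        auc = NA_real_, brier = NA_real_,
                        hl_stat = NA_real_, hl_p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    p <- pr[, cl]
    hl <- tryCatch(hosmer_lemeshow(p, y),
                   error = function(e) list(statistic = NA_real_,
                                            p_value = NA_real_))
    data.frame(class = cl, n = nrow(d), events = sum(y),
               auc = auc_rank(p, y),
               brier = mean((p - as.numeric(y))^2),
               hl_stat = hl$statistic, hl_p = hl$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Temporal-split cross-validation
#'
#' Trains on subjects enrolled before `split_day` and evaluates on subjects
#' enrolled at or after it — the deployment-like split that prevents
#' optimistic bias from cohort drift.
#'
#' @param outcomes data.frame from [build_horizon_outcomes()].
#' @param predictors predictor table with an `enroll_day` column (merge of
#'   indices and subject table).
#' @param split_day enrollment-day cutoff.
#' @param predictor_cols predictors used in the model.
#' @return list: `report` (test-set [evaluate_predictions()] output),
#'   `n_train`, `n_test`.
#' @export
temporal_split_cv <- function(outcomes, predictors, split_day,
                              predictor_cols = "fdg_z") {
  train_ids <- predictors$subject_id[predictors$enroll_day < split_day]
  test_ids <- predictors$subject_id[predictors$enroll_day >= split_day]
  otr <- outcomes[outcomes$subject_id %in% train_ids, ]
  ote <- outcomes[outcomes$subject_id %in% test_ids, ]
  if (!nrow(otr) || !nrow(ote)) stop("empty side of the temporal split")
  model <- fit_multinomial(otr, predictors, predictor_cols)
  list(report = evaluate_predictions(model, ote, predictors),
       n_train = length(train_ids), n_test = length(test_ids))
}

#' Subject-grouped k-fold cross-validation
#'
#' Folds partition subjects (never rows), so no subject contributes to both
#' the training and test side of any fold.  Metrics missing a class in a
#' fold are reported missing for that fold.
#'
#' @param outcomes data.frame from [build_horizon_outcomes()].
#' @param predictors predictor table keyed by subject_id.
#' @param k number of folds.
#' @param seed RNG seed for the fold assignment.
#' @param predictor_cols predictors used in the model.
#' @return list: `folds` (per-fold reports), `fold_assignment` (named
#'   integer vector by subject), `mean_auc` (per-class mean over folds).
#' @export
grouped_kfold_cv <- function(outcomes, predictors, k = 5, seed = 1L,
                             predictor_cols = "fdg_z") {
  ids <- unique(outcomes$subject_id)
  stopifnot(k >= 2, k <= length(ids))
  set.seed(seed)
  fold <- stats::setNames(sample(rep_len(seq_len(k), length(ids))), ids)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    te_ids <- ids[fold[ids] == f]
    otr <- outcomes[!outcomes$subject_id %in% te_ids, ]
    ote <- outcomes[outcomes$subject_id %in% te_ids, ]
    reports[[f]] <- tryCatch({
      model <- fit_multinomial(otr, predictors, predictor_cols)
      evaluate_predictions(model, ote, predictors)
    }, error = function(e) NULL)
  }
  aucs <- lapply(HORIZON_CLASSES, function(cl) {
    vals <- vapply(reports, function(r) {
      if (is.null(r) || !cl %in% r$class) NA_real_
      else r$auc[r$class == cl]
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  })
  list(folds = reports, fold_assignment = fold,
       mean_auc = stats::setNames(unlist(aucs), HORIZON_CLASSES))
}

#' Predicted pathway probabilities at representative FDG levels
#'
#' Evaluates the fitted model at representative z-scores per FDG category
#' (defaults: low = -1, average = 0, high = +1) and reports percentages
#' (each row sums to 100).
#'
#' @param model a `"pathway_multinom"` model (FDG-only predictors).
#' @param z_rep named vector of representative z values.
#' @return data.frame: fdg_level, one percentage column per class.
#' @export
probability_by_fdg_category <- function(model,
                                        z_rep = c(low = -1, average = 0,
                                                  high = 1)) {
  nd <- data.frame(fdg_z = unname(z_rep))
  pr <- predict(model, nd) * 100
  out <- data.frame(fdg_level = names(z_rep), stringsAsFactors = FALSE)
  for (cl in colnames(pr)) out[[cl]] <- pr[, cl]
  out
}
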