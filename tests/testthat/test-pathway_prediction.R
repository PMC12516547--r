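mk_assignment <- function(id, label, t_event, t_censor,
                          mci_day = NA, ad_day = NA) {
  data.frame(subject_id = id, label = label, t_first_event_days = t_event,
             t_censor_days = t_censor, confirmed_mci_day = mci_day,
             confirmed_ad_day = ad_day, reversion_count = 0L,
             stringsAsFactors = FALSE)
}

test_that("horizon outcomes follow the first-event rule and censoring", {
  asg <- rbind(
    mk_assignment("a", "DIRECT_AD", 300, 300, ad_day = 300),
    mk_assignment("b", "STABLE", NA, 200),
    mk_assignment("c", "MCI_TO_AD", 500, 900, mci_day = 500, ad_day = 900),
    mk_assignment("d", "STABLE", NA, 1200))
  oc12 <- build_horizon_outcomes(asg, 12)
  expect_equal(as.character(oc12$label[oc12$subject_id == "a"]),
               "DIRECT_AD")
  expect_false(oc12$known[oc12$subject_id == "b"])
  oc24 <- build_horizon_outcomes(asg, 24)
  expect_equal(as.character(oc24$label[oc24$subject_id == "c"]),
               "MCI_FIRST")
  expect_equal(as.character(oc24$label[oc24$subject_id == "d"]), "STABLE")
  expect_true(oc24$known[oc24$subject_id == "d"])
})

test_that("multinomial reduces to binary logistic regression", {
  set.seed(3)
  n <- 400
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * z))
  oc <- data.frame(subject_id = as.character(1:n), horizon_months = 24,
                   label = factor(ifelse(y == 1, "DIRECT_AD", "STABLE"),
                                  levels = c("STABLE", "MCI_FIRST",
                                             "DIRECT_AD")),
                   known = TRUE, stringsAsFactors = FALSE)
  pred <- data.frame(subject_id = as.character(1:n), fdg_z = z,
                     stringsAsFactors = FALSE)
  fit <- fit_multinomial(oc, pred)
  g <- glm(y ~ z, family = binomial)
  expect_equal(unname(summary(fit$fit)$coefficients),
               unname(coef(g)), tolerance = 1e-4)
  pr <- predict(fit, data.frame(fdg_z = c(-1, 0, 1)))
  expect_equal(unname(rowSums(pr)), rep(1, 3), tolerance = 1e-12)
})

test_that("multinomial recovers generating softmax coefficients", {
  set.seed(6)
  n <- 5000
  z <- rnorm(n)
  b_mci <- c(0.2, -0.5); b_ad <- c(-1.0, -1.5)
  den <- 1 + exp(b_mci[1] + b_mci[2] * z) + exp(b_ad[1] + b_ad[2] * z)
  p_st <- 1 / den
  p_mci <- exp(b_mci[1] + b_mci[2] * z) / den
  u <- runif(n)
  lab <- ifelse(u < p_st, "STABLE",
         ifelse(u < p_st + p_mci, "MCI_FIRST", "DIRECT_AD"))
  oc <- data.frame(subject_id = as.character(1:n), horizon_months = 24,
                   label = factor(lab, levels = c("STABLE", "MCI_FIRST",
                                                  "DIRECT_AD")),
                   known = TRUE, stringsAsFactors = FALSE)
  pred <- data.frame(subject_id = as.character(1:n), fdg_z = z,
                     stringsAsFactors = FALSE)
  fit <- fit_multinomial(oc, pred)
  co <- summary(fit$fit)$coefficients
  expect_lt(max(abs(co["MCI_FIRST", ] - b_mci) / abs(b_mci)), 0.25)
  expect_lt(max(abs(co["DIRECT_AD", ] - b_ad) / abs(b_ad)), 0.25)
})

test_that("constant predictor leaves intercepts reproducing class frequencies", {
  set.seed(8)
  n <- 600
  lab <- sample(c("STABLE", "MCI_FIRST", "DIRECT_AD"), n, replace = TRUE,
                prob = c(0.5, 0.3, 0.2))
  oc <- data.frame(subject_id = as.character(1:n), horizon_months = 24,
                   label = factor(lab, levels = c("STABLE", "MCI_FIRST",
                                                  "DIRECT_AD")),
                   known = TRUE, stringsAsFactors = FALSE)
  pred <- data.frame(subject_id = as.character(1:n), fdg_z = rnorm(n),
                     stringsAsFactors = FALSE)
  # shuffle-independent predictor: probabilities ~ class frequencies
  fit <- fit_multinomial(oc, pred)
  pr <- predict(fit, data.frame(fdg_z = 0))
  expect_equal(unname(pr[1, ]), as.vector(table(lab)[fit$classes] / n),
               tolerance = 0.06)
})

test_that("rank AUC equals exhaustive pairwise comparison and Brier is exact", {
  set.seed(9)
  n <- 150
  score <- round(rnorm(n), 1)  # rounding forces ties
  y <- rbinom(n, 1, plogis(score)) == 1
  brute <- {
    pos <- score[y]; neg <- score[!y]
    s <- 0
    for (a in pos) s <- s + sum(a > neg) + 0.5 * sum(a == neg)
    s / (length(pos) * length(neg))
  }
  expect_equal(auc_rank(score, y), brute, tolerance = 1e-12)
  expect_equal(auc_rank(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  # AUC is invariant under monotone transforms of the score
  expect_equal(auc_rank(exp(score), y), auc_rank(score, y))
  # all-0.5 predictions on balanced binary data give Brier 0.25
  expect_equal(mean((rep(0.5, 10) - rep(c(0, 1), 5))^2), 0.25)
})

test_that("evaluation reports per-class AUC/Brier/HL on a simulated fit", {
  s <- sim_eligible(n = 400, seed = 43)
  asg <- classify_cohort(s$eligible)
  idx <- compute_indices(s$eligible)
  oc <- build_horizon_outcomes(asg, 24)
  fit <- fit_multinomial(oc, idx)
  ev <- evaluate_predictions(fit, oc, idx)
  expect_true(all(ev$auc >= 0 & ev$auc <= 1, na.rm = TRUE))
  expect_true(all(ev$brier >= 0 & ev$brier <= 1, na.rm = TRUE))
  expect_gt(ev$auc[ev$class == "DIRECT_AD"], 0.5)
})

test_that("grouped k-fold CV never leaks a subject across the split", {
  s <- sim_eligible(n = 300, seed = 47)
  asg <- classify_cohort(s$eligible)
  idx <- compute_indices(s$eligible)
  oc <- build_horizon_outcomes(asg, 24)
  cv <- grouped_kfold_cv(oc, idx, k = 5, seed = 2)
  fold <- cv$fold_assignment
  for (f in 1:5) {
    te <- names(fold)[fold == f]
    tr <- names(fold)[fold != f]
    expect_length(intersect(te, tr), 0)
  }
  expect_true(all(table(fold) >= 1))
  # strong simulated FDG effect: out-of-sample direct-AD discrimination
  expect_gt(cv$mean_auc[["DIRECT_AD"]], 0.65)
})

test_that("temporal split trains strictly before and tests after the cut", {
  s <- sim_eligible(n = 400, seed = 53)
  asg <- classify_cohort(s$eligible)
  idx <- compute_indices(s$eligible)
  idx$enroll_day <- s$eligible$subjects$enroll_day[
    match(idx$subject_id, s$eligible$subjects$subject_id)]
  oc <- build_horizon_outcomes(asg, 24)
  res <- temporal_split_cv(oc, idx, split_day = 900)
  expect_gt(res$n_train, 0)
  expect_gt(res$n_test, 0)
  expect_equal(res$n_train + res$n_test, nrow(idx))
  expect_error(temporal_split_cv(oc, idx, split_day = -1), "empty side")
})

test_that("probability table rows sum to 100 and risk falls with metabolism", {
  s <- sim_eligible(n = 500, seed = 59)
  asg <- classify_cohort(s$eligible)
  idx <- compute_indices(s$eligible)
  fit <- fit_multinomial(build_horizon_outcomes(asg, 24), idx)
  tab <- probability_by_fdg_category(fit)
  num <- as.matrix(tab[, fit$classes])
  expect_equal(unname(rowSums(num)), rep(100, 3), tolerance = 1e-9)
  if ("DIRECT_AD" %in% fit$classes) {
    expect_gt(tab$DIRECT_AD[tab$fdg_level == "low"],
              tab$DIRECT_AD[tab$fdg_level == "high"])
  }
})
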