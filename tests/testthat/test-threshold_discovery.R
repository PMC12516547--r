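test_that("ROC handles separation, ties to Mann-Whitney, monotone transforms", {
  r <- roc_curve(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  set.seed(2)
  score <- round(rnorm(120), 1)
  y <- rbinom(120, 1, plogis(1.5 * score)) == 1
  r2 <- roc_curve(score, y)
  expect_equal(r2$auc, auc_rank(score, y), tolerance = 1e-12)
  r3 <- roc_curve(qlogis(plogis(score)), y)  # monotone transform
  expect_equal(r3$auc, r2$auc, tolerance = 1e-9)
  expect_true(all(diff(r2$sensitivity) >= 0))  # thresholds loosen downward
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("permuted labels give chance-level AUC", {
  set.seed(21)
  aucs <- replicate(40, {
    score <- rnorm(150)
    roc_curve(score, sample(rep(c(TRUE, FALSE), 75)))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("Youden optimum equals the brute-force cutpoint sweep", {
  set.seed(22)
  for (rep in 1:5) {
    score <- round(rnorm(300), 1)
    y <- rbinom(300, 1, plogis(2 * score)) == 1
    yo <- youden_optimal(roc_curve(score, y))
    brute <- max(sapply(unique(score), function(c0) {
      sum(score >= c0 & y) / sum(y) + sum(score < c0 & !y) / sum(!y) - 1
    }))
    expect_equal(yo$youden_j, brute, tolerance = 1e-12)
    expect_equal(yo$youden_j, yo$sensitivity + yo$specificity - 1,
                 tolerance = 1e-12)
  }
  expect_equal(youden_optimal(roc_curve(c(0, 1), c(FALSE, TRUE)))$youden_j,
               1)
})

test_that("reported operating points satisfy the Youden identity", {
  y <- reference_estimates$youden
  expect_equal(y$direct_high_risk[["sensitivity"]] +
                 y$direct_high_risk[["specificity"]] - 1, 0.60)
  expect_equal(y$stability_vs_decline[["sensitivity"]] +
                 y$stability_vs_decline[["specificity"]] - 1, 0.41)
})

test_that("contrast suite orders cutpoints and handles degenerate arms", {
  s <- sim_eligible(n = 600, seed = 61)
  asg <- classify_cohort(s$eligible)
  idx <- compute_indices(s$eligible)
  z <- setNames(idx$fdg_z, idx$subject_id)
  cs <- contrast_suite(asg, z)
  expect_setequal(cs$contrast, c("stability_vs_decline",
                                 "sequential_vs_direct",
                                 "direct_vs_rest"))
  expect_true(all(cs$youden_j >= 0 & cs$youden_j <= 1))
  expect_equal(cs$youden_j, cs$sensitivity + cs$specificity - 1,
               tolerance = 1e-12)

  # cohort with a single decliner type: the sequential-vs-direct arm is
  # reported missing rather than erroring
  one_type <- asg[asg$label %in% c("STABLE", "DIRECT_AD"), ]
  cs2 <- contrast_suite(one_type, z)
  expect_true(is.na(
    cs2$cutpoint_z[cs2$contrast == "sequential_vs_direct"]))
})

test_that("direct-conversion cutpoint sits below the any-decline cutpoint", {
  # Youden cutpoints are noisy in any single cohort; the ordering is a
  # property of the expected operating points, so test it on the average
  # over independent calibrated cohorts
  diffs <- vapply(1:5, function(s) {
    sim <- simulate_cohort(default_params_paper_like(seed = 700 + s))
    el <- eligibility_filter(sim$cohort)$cohort
    asg <- classify_cohort(el)
    idx <- compute_indices(el)
    cs <- contrast_suite(asg, setNames(idx$fdg_z, idx$subject_id))
    cs$cutpoint_z[cs$contrast == "direct_vs_rest"] -
      cs$cutpoint_z[cs$contrast == "stability_vs_decline"]
  }, numeric(1))
  expect_lt(mean(diffs), 0)
})

test_that("no FDG effect gives near-zero Youden indices", {
  s <- sim_eligible(n = 500, seed = 67,
                    transition_coeffs = list(cn_mci = c(-1.8, 0),
                                             cn_ad = c(-3.0, 0),
                                             mci_ad = c(-2.0, 0)))
  asg <- classify_cohort(s$eligible)
  idx <- compute_indices(s$eligible)
  cs <- contrast_suite(asg, setNames(idx$fdg_z, idx$subject_id))
  expect_true(all(cs$youden_j < 0.2, na.rm = TRUE))
})

test_that("dose-response bins partition the cohort and sum to 100%", {
  s <- sim_eligible(n = 600, seed = 71)
  asg <- classify_cohort(s$eligible)
  idx <- compute_indices(s$eligible)
  z <- setNames(idx$fdg_z, idx$subject_id)
  dr <- dose_response_bins(z, asg)
  expect_equal(sum(dr$n), nrow(asg))
  nonempty <- dr$n > 0
  expect_equal(unname(rowSums(dr[nonempty,
                                 c("pct_stable", "pct_mci_only",
                                   "pct_mci_to_ad", "pct_direct_ad")])),
               rep(100, sum(nonempty)), tolerance = 1e-9)
  # strong metabolic effect: direct-conversion share falls across bins
  dd <- dr$pct_direct_ad[nonempty]
  expect_lt(suppressWarnings(
    cor(seq_along(dd), dd, method = "spearman")), 0)
  # single-bin edge case reproduces whole-cohort proportions
  dr1 <- dose_response_bins(z, asg, bin_edges = 99)
  expect_equal(dr1$pct_direct_ad[1], 100 * mean(asg$label == "DIRECT_AD"))
  expect_error(dose_response_bins(z, asg, bin_edges = c(1, 1)))
})
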