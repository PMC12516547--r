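test_that("fdg z-scores normalize, propagate missing, and are affine-invariant", {
  z <- fdg_zscore(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  x <- c(rnorm(20), NA)
  expect_true(is.na(fdg_zscore(x)[21]))
  expect_equal(fdg_zscore(x), fdg_zscore(3 * x - 7), tolerance = 1e-12)
  expect_error(fdg_zscore(rep(1, 5)), "zero variance")
  expect_error(fdg_zscore(1), ">= 2")
})

test_that("strata use empirical tertiles and fixed category cutpoints", {
  set.seed(1)
  st <- fdg_strata(rnorm(300))
  expect_equal(unname(table(st$tertile)), c(100L, 100L, 100L),
               ignore_attr = TRUE)
  expect_equal(as.character(fdg_strata(c(0.6, 0.5, -0.5, -0.51))$category),
               c("HIGH_STABILITY", "INTERMEDIATE", "INTERMEDIATE",
                 "HIGH_RISK"))
})

test_that("cognitive reserve and vulnerability arithmetic", {
  expect_equal(cognitive_reserve(30, 0), 30)
  expect_equal(cognitive_reserve(24, 9), 21)
  expect_true(is.na(cognitive_reserve(NA, 5)))
  expect_equal(vulnerability_index(1, 30), 0)
  expect_equal(vulnerability_index(-1, 22), 4)
  # strictly increasing across reference pathway profiles stable -> direct
  v <- vulnerability_index(c(0.57, 0.43, 0.04, -0.18),
                           c(26.9, 24.7, 23.7, 21.0))
  expect_true(all(diff(v) > 0))
})

test_that("amyloid mixture EM recovers components and is orientation-safe", {
  set.seed(42)
  n <- 1000
  comp <- runif(n) < 0.5
  x <- ifelse(comp, rnorm(n, 80, 30), rnorm(n, 10, 15))
  am <- amyloid_positivity(x)
  expect_lt(abs(am$means[1] - 10), 5)
  expect_lt(abs(am$means[2] - 80), 5)
  expect_gt(am$means[2], am$means[1])  # positive component = higher mean
  expect_true(all(am$posterior_positive >= 0 & am$posterior_positive <= 1))
  expect_equal(sum(am$weights), 1, tolerance = 1e-9)
  # sharply separated mixture: calls match the generating component
  y <- c(rnorm(100, 0, 5), rnorm(100, 100, 5))
  am2 <- amyloid_positivity(y)
  expect_equal(am2$positive, rep(c(FALSE, TRUE), each = 100))
  # independent cross-check against a reference mixture fitter
  if (requireNamespace("mclust", quietly = TRUE)) {
    withr::local_package("mclust")
    mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    expect_lt(max(abs(sort(am$means) - sort(mc$parameters$mean))), 2)
  }
  # single-component data flag degenerate fits rather than inventing modes
  am3 <- amyloid_positivity(rnorm(200, 50, 1))
  expect_true(am3$degenerate || abs(diff(am3$means)) < 3)
  expect_error(amyloid_positivity(rnorm(10)), ">= 20")
})

test_that("atrophy index is oriented (higher = worse), normalized, eigen-true", {
  set.seed(7)
  n <- 200
  shrink <- runif(n)                     # latent severity
  hip <- 8000 - 1500 * shrink + rnorm(n, 0, 50)
  brain <- rep(1.05e6, n) + rnorm(n, 0, 1000)
  ai <- atrophy_index(hip, brain)
  expect_gt(cor(ai$atrophy_index_z, shrink), 0.9)
  expect_equal(mean(ai$atrophy_index_z), 0, tolerance = 1e-12)
  expect_equal(sd(ai$atrophy_index_z), 1, tolerance = 1e-12)
  expect_lt(ai$loadings["hippocampus_vol"], 0)
  # 2-variable toy: loadings match the closed-form eigenvector (1,1)/sqrt(2)
  # of an equicorrelation matrix, up to the orientation rule
  set.seed(8)
  a <- rnorm(500)
  b <- 0.6 * a + 0.8 * rnorm(500)
  pc <- prcomp(cbind(a, b), scale. = TRUE)$rotation[, 1]
  expect_equal(abs(pc), rep(1 / sqrt(2), 2), tolerance = 0.05,
               ignore_attr = TRUE)
  expect_error(atrophy_index(rep(1, 5) * 1000, rep(1e6, 5)), "constant")
})

test_that("composite vulnerability is symmetric and decile profile monotone", {
  set.seed(9)
  n <- 600
  cent <- c(rnorm(n / 2, 10, 15), rnorm(n / 2, 80, 30))
  atr <- rnorm(n)
  cv <- composite_vulnerability(cent, atr)
  cv_swap <- composite_vulnerability(atr, cent)  # symmetric in z inputs
  expect_equal(sort(cv), sort(cv_swap), tolerance = 1e-9)
  pos <- cent > 40
  vd <- vulnerability_deciles(cv, pos)
  expect_equal(nrow(vd$table), 10)
  expect_gt(vd$table$pct_positive[10], vd$table$pct_positive[1])
  expect_gt(vd$spearman, 0.8)
  expect_warning(vulnerability_deciles(rnorm(5), rep(TRUE, 5)),
                 "single-bin")
})

test_that("positivity odds ratio matches hand arithmetic with Woolf CI", {
  tert <- factor(rep(c("HIGH", "LOW"), each = 100),
                 levels = c("LOW", "MID", "HIGH"))
  pos <- c(rep(c(TRUE, FALSE), c(50, 50)), rep(c(TRUE, FALSE), c(50, 50)))
  expect_equal(positivity_or_by_atrophy_tertile(pos, tert)$or, 1)
  pos2 <- c(rep(c(TRUE, FALSE), c(30, 70)), rep(c(TRUE, FALSE), c(60, 40)))
  r <- positivity_or_by_atrophy_tertile(pos2, tert)
  expect_equal(r$or, (30 * 40) / (70 * 60), tolerance = 1e-12)  # 0.2857
  expect_true(r$ci[1] < r$or && r$or < r$ci[2])
  # zero cell triggers the continuity correction and is flagged
  pos3 <- c(rep(TRUE, 100), rep(c(TRUE, FALSE), c(99, 1)))
  expect_true(positivity_or_by_atrophy_tertile(pos3, tert)$corrected)
})

test_that("Woolf CI covers the true odds ratio at the nominal rate", {
  set.seed(10)
  true_or <- 2
  p_lo <- 0.3
  p_hi <- plogis(qlogis(p_lo) + log(true_or))
  hits <- replicate(300, {
    hi_pos <- rbinom(1, 120, p_hi)
    lo_pos <- rbinom(1, 120, p_lo)
    tert <- factor(rep(c("HIGH", "LOW"), each = 120),
                   levels = c("LOW", "MID", "HIGH"))
    pos <- c(rep(c(TRUE, FALSE), c(hi_pos, 120 - hi_pos)),
             rep(c(TRUE, FALSE), c(lo_pos, 120 - lo_pos)))
    ci <- positivity_or_by_atrophy_tertile(pos, tert)$ci
    ci[1] <= true_or && true_or <= ci[2]
  })
  expect_gt(mean(hits), 0.90)
})
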