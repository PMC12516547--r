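test_that("confirmation rule handles fluctuation, confirmation and escalation", {
  # isolated MCI that reverts: ignored, counted as a reversion
  cf <- confirm_transitions(c(0, 365, 540, 900), c("CN", "MCI", "CN", "CN"))
  expect_true(is.na(cf$confirmed_mci_day))
  expect_equal(cf$reversion_count, 1L)

  # straightforward confirmation at the first carrying visit
  cf <- confirm_transitions(c(0, 365, 730), c("CN", "MCI", "MCI"))
  expect_equal(cf$confirmed_mci_day, 365)

  # a worse diagnosis confirms the milder one, then itself terminally
  cf <- confirm_transitions(c(0, 365, 730), c("CN", "MCI", "AD"))
  expect_equal(cf$confirmed_mci_day, 365)
  expect_equal(cf$confirmed_ad_day, 730)

  # terminal worsening without lookahead is rejected when the flag is off
  cf <- confirm_transitions(c(0, 365, 730), c("CN", "MCI", "AD"),
                            accept_terminal = FALSE)
  expect_equal(cf$confirmed_mci_day, 365)
  expect_true(is.na(cf$confirmed_ad_day))

  expect_error(confirm_transitions(numeric(0), character(0)), "empty")
})

test_that("reversions never un-confirm a state (ratchet)", {
  cf <- confirm_transitions(c(0, 365, 730, 1100, 1460),
                            c("CN", "MCI", "MCI", "CN", "CN"))
  expect_equal(cf$confirmed_mci_day, 365)
  expect_equal(cf$confirmed[4:5], c("MCI", "MCI"))
})

test_that("classification covers the four pathways with correct event times", {
  a <- classify_subject("s", c(0, 365, 730, 1100), rep("CN", 4))
  expect_equal(a$label, "STABLE")
  expect_true(is.na(a$t_first_event_days))
  expect_equal(a$t_censor_days, 1100)

  a <- classify_subject("s", c(0, 400, 760), c("CN", "AD", "AD"))
  expect_equal(a$label, "DIRECT_AD")
  expect_equal(a$t_first_event_days, 400)
  expect_true(is.na(a$confirmed_mci_day))

  a <- classify_subject("s", c(0, 365, 730, 1100, 1460),
                        c("CN", "MCI", "MCI", "AD", "AD"))
  expect_equal(a$label, "MCI_TO_AD")
  expect_equal(a$t_first_event_days, 365)
  expect_lt(a$confirmed_mci_day, a$confirmed_ad_day)

  a <- classify_subject("s", c(0, 365, 730), c("CN", "MCI", "MCI"))
  expect_equal(a$label, "MCI_ONLY")

  # an MCI visit without 180-day confirmation before terminal dementia
  # still reads as direct conversion
  a <- classify_subject("s", c(0, 300, 400), c("CN", "MCI", "AD"))
  expect_equal(a$label, "DIRECT_AD")
  expect_equal(a$reversion_count, 1L)
})

test_that("labels partition eligible subjects", {
  s <- sim_eligible(n = 300, seed = 23)
  asg <- classify_cohort(s$eligible)
  expect_equal(nrow(asg), nrow(s$eligible$subjects))
  expect_equal(anyDuplicated(asg$subject_id), 0L)
  expect_true(all(asg$label %in%
                    c("STABLE", "MCI_ONLY", "MCI_TO_AD", "DIRECT_AD")))
  expect_equal(sum(table(asg$label)), nrow(asg))
})

test_that("lengthening follow-up only moves subjects forward", {
  s <- sim_eligible(n = 150, seed = 29)
  full <- s$eligible
  asg_full <- classify_cohort(full)
  # truncate everyone to five years and compare
  vis5 <- full$visits[full$visits$day <= 1826, ]
  keep <- names(which(tapply(vis5$day, vis5$subject_id, max) >= 180))
  x5 <- cohort(full$subjects[full$subjects$subject_id %in% keep, ],
               vis5[vis5$subject_id %in% keep, ])
  asg5 <- classify_cohort(x5)
  rank_of <- c(STABLE = 0, MCI_ONLY = 1, MCI_TO_AD = 2, DIRECT_AD = 2)
  m <- match(asg5$subject_id, asg_full$subject_id)
  expect_true(all(rank_of[asg_full$label[m]] >= rank_of[asg5$label]))
  # a direct converter never becomes sequential later and vice versa once
  # the first confirmed event is set
  both <- !is.na(asg5$t_first_event_days)
  expect_true(all(asg5$t_first_event_days[both] ==
                    asg_full$t_first_event_days[m][both]))
})

test_that("with min_confirm_days = 0 every observed worsening confirms", {
  cf <- confirm_transitions(c(0, 100, 200), c("CN", "MCI", "CN"),
                            min_confirm_days = 0)
  expect_equal(cf$confirmed_mci_day, 100)
  expect_equal(cf$reversion_count, 0L)
})

test_that("pathway summary reproduces the printed metabolic gradients", {
  # per-pathway FDG means reported by the reference analysis
  fm <- reference_estimates$fdg_means
  ids <- sprintf("p%d", 1:4)
  asg <- data.frame(subject_id = ids,
                    label = c("STABLE", "MCI_ONLY", "MCI_TO_AD",
                              "DIRECT_AD"),
                    t_first_event_days = c(NA, 400, 400, 400),
                    t_censor_days = 3000, confirmed_mci_day = NA,
                    confirmed_ad_day = NA, reversion_count = 0L,
                    stringsAsFactors = FALSE)
  sm <- pathway_summary(asg, setNames(unname(fm), ids))
  expect_equal(sm$gradient_sd, 0.75)
  expect_equal(sm$switching_gap_sd, 0.61)
})

test_that("empty pathways report missing statistics, not zero", {
  asg <- classify_cohort(cohort(
    subject_row("a"), visit_rows("a", c(0, 400), c("CN", "CN"))))
  sm <- pathway_summary(asg, c(a = 0.5))
  expect_equal(sm$table$n[sm$table$pathway == "DIRECT_AD"], 0L)
  expect_true(is.na(sm$table$fdg_mean[sm$table$pathway == "DIRECT_AD"]))
})
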