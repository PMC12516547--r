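# In-code fixtures shared across test files.

subject_row <- function(id, fdg = 1.2, centiloid = 20, hip = 7000,
                        brain = 1.05e6, age = 72, enroll = 0) {
  data.frame(subject_id = id, age_baseline = age, fdg_raw = fdg,
             centiloid = centiloid, hippocampus_vol = hip,
             brain_vol = brain, enroll_day = enroll,
             stringsAsFactors = FALSE)
}

visit_rows <- function(id, days, dx, mmse = NA_integer_, adas = NA_real_) {
  data.frame(subject_id = id, day = days, diagnosis = dx,
             mmse = rep_len(mmse, length(days)),
             adas = rep_len(adas, length(days)), stringsAsFactors = FALSE)
}

# two-subject toy cohort: one stable, one direct converter
toy_cohort <- function() {
  cohort(
    rbind(subject_row("a", fdg = 1.4), subject_row("b", fdg = 1.0)),
    rbind(visit_rows("a", c(0, 365, 730), c("CN", "CN", "CN"), mmse = 29,
                     adas = 6),
          visit_rows("b", c(0, 400, 760), c("CN", "AD", "AD"), mmse = 27,
                     adas = 10)))
}

# deterministic mid-size simulated cohort for integration-style tests
sim_eligible <- function(n = 400, seed = 11, ...) {
  p <- simulation_params(n_subjects = n, seed = seed, ...)
  sim <- simulate_cohort(p)
  list(eligible = eligibility_filter(sim$cohort)$cohort,
       truth = sim$truth, raw = sim$cohort)
}
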