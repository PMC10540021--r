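test_that("schedule counts are exact for every regime", {
  expect_length(generate_schedule(ema_regime("daily", weeks = 12)), 84L)
  expect_length(generate_schedule(ema_regime("thrice_daily", weeks = 12)),
                252L)
  expect_length(generate_schedule(ema_regime("thrice_weekly", weeks = 12)),
                36L)
  expect_length(generate_schedule(ema_regime("daily", weeks = 0)), 0L)

  # one week of thrice-weekly lands on Mon/Wed/Fri at the default time
  s <- generate_schedule(ema_regime("thrice_weekly", weeks = 1,
                                    start = as.Date("2022-07-18")))
  expect_length(s, 3L)
  expect_identical(format(s, "%u"), c("1", "3", "5"))
  expect_identical(unique(format(s, "%H:%M")), "09:00")

  # timestamps are sorted and unique in all regimes
  for (kind in c("thrice_weekly", "daily", "thrice_daily")) {
    s <- generate_schedule(ema_regime(kind, weeks = 4))
    expect_false(is.unsorted(s, strictly = TRUE))
  }
})

test_that("recovery trajectories decay from baseline to asymptote", {
  p <- trajectory_profile("recovery", baseline = 1.5, asymptote = -1,
                          rate = 0.05)
  expect_equal(latent_theta_at(p, 0), 1.5)
  expect_equal(latent_theta_at(p, 1e6), -1)
  th <- latent_theta_at(p, seq(0, 84, by = 1))
  expect_true(all(diff(th) < 0))  # monotone improvement, no noise term
})

test_that("fluctuating trajectories dip after an intervention and rebound", {
  p <- trajectory_profile("fluctuating", baseline = 1, ar_sd = 0,
                          diurnal_amplitude = 0,
                          intervention = list(time = 20, depth = 1.2,
                                              rebound_days = 10))
  tgrid <- seq(0, 50, by = 0.05)
  th <- latent_theta_at(p, tgrid)
  tmin <- tgrid[which.min(th)]
  expect_gt(tmin, 20); expect_lte(tmin, 30)
  expect_equal(min(th), 1 - 1.2)
  # back within 10% of baseline at the end of the rebound window
  expect_lt(abs(th[tgrid == 30] - 1), 0.1 * 1)
  expect_equal(th[tgrid == 40], 1)

  # diurnal term peaks in the evening and is centred on the baseline
  pd <- trajectory_profile("fluctuating", baseline = 0.5, ar_sd = 0,
                           diurnal_amplitude = 0.3)
  day <- seq(0, 1, by = 1 / 48)
  thd <- latent_theta_at(pd, day)
  expect_equal(max(thd), 0.8, tolerance = 1e-6)
  expect_equal(min(thd), 0.2, tolerance = 1e-6)

  # AR(1) noise is reproducible and does not leak RNG state
  pn <- trajectory_profile("fluctuating", baseline = 0, ar_sd = 0.25)
  n1 <- latent_theta_at(pn, 1:30, seed = 9)
  n2 <- latent_theta_at(pn, 1:30, seed = 9)
  expect_identical(n1, n2)
  expect_gt(stats::sd(n1), 0)
  # lag-1 autocorrelation is positive for a persistent process
  expect_gt(stats::cor(n1[-1], n1[-30]), 0)
})

test_that("simulated responses follow the measurement model", {
  bank <- toy_bank()
  set.seed(123)
  draws <- replicate(20000, simulate_response(0.3, bank, "t1"))
  p <- grm_category_probs(0.3, bank, "t1")
  freq <- tabulate(draws, nbins = 4) / 20000
  se <- sqrt(p * (1 - p) / 20000)
  expect_true(all(abs(freq - p) < 3 * se + 1e-12))

  # degenerate limit: far above the top threshold, top category
  steep <- item_bank("s", a = 40, thresholds = list(c(-1, 0, 1)))
  set.seed(5)
  expect_identical(unique(replicate(50, simulate_response(4, steep, "s"))),
                   4L)

  # fixed seed reproduces the category
  set.seed(77); k1 <- simulate_response(0, bank, "t2")
  set.seed(77); k2 <- simulate_response(0, bank, "t2")
  expect_identical(k1, k2)
})

test_that("study runs honour compliance and chain dynamic priors", {
  bank <- simulate_item_bank()
  reg <- ema_regime("daily", weeks = 1)
  full <- sim_respondent("p1", trajectory_profile("recovery"),
                         reg, compliance = 1, seed = 2)
  none <- sim_respondent("p2", trajectory_profile("recovery"),
                         reg, compliance = 0, seed = 3)
  study <- run_study(list(full, none), bank,
                     full_length_weeks = numeric(0), seed = 42)
  n1 <- sum(study$assessments$participant_id == "p1")
  expect_identical(n1, 7L)
  expect_false("p2" %in% study$assessments$participant_id)
  ss <- summarize_study(study)
  rates <- ss$response_rates
  expect_identical(rates$rate[rates$participant_id == "p1"], 1)
  expect_identical(rates$rate[rates$participant_id == "p2"], 0)

  # whole-study bit-reproducibility under one master seed
  study2 <- run_study(list(full, none), bank,
                      full_length_weeks = numeric(0), seed = 42)
  expect_identical(study, study2)

  # every SE-rule termination is below the threshold; min one item
  expect_true(all(study$assessments$se[
    study$assessments$termination_reason == "se_met"] < 0.3))
  expect_true(all(study$assessments$n_items >= 1L))

  expect_error(run_study(list(), bank), "empty cohort")
})

test_that("dynamic priors do not lengthen assessments versus static priors", {
  bank <- simulate_item_bank()
  reg <- ema_regime("daily", weeks = 2)
  # slowly drifting severity, no occasion noise
  resp <- sim_respondent("p1",
                         trajectory_profile("recovery", baseline = 0.8,
                                            asymptote = 0.2, rate = 0.02),
                         reg, compliance = 1, seed = 4)
  dyn <- run_study(list(resp), bank,
                   cat_control(prior_policy = "dynamic"),
                   full_length_weeks = numeric(0), seed = 99)
  sta <- run_study(list(resp), bank,
                   cat_control(prior_policy = "static"),
                   full_length_weeks = numeric(0), seed = 99)
  expect_lte(mean(dyn$assessments$n_items),
             mean(sta$assessments$n_items))
  # after the first assessment, carried priors start informative
  expect_gt(mean(sta$assessments$n_items[-1]), 1)
})

test_that("study summaries conserve exposure counts and report items used", {
  bank <- simulate_item_bank()
  cohort <- simulate_cohort(c(daily = 3), c(daily = 0.8),
                            weeks = 2, seed = 10)
  study <- run_study(cohort, bank, seed = 7)
  ss <- summarize_study(study)
  expect_identical(sum(ss$exposure$times_administered),
                   sum(study$assessments$n_items))
  expect_identical(sum(ss$exposure$times_administered),
                   nrow(study$response_log))
  expect_true(ss$items_per_assessment$median >= 1)
  expect_true(all(ss$response_rates$rate >= 0 &
                    ss$response_rates$rate <= 1))
  expect_gt(ss$median_delay_min, 0)
})

test_that("CAT versus full-length comparison computes the error statistics", {
  # hand-checkable arithmetic on pre-formed pairs
  pairs <- data.frame(cat_eap = c(0.5, -0.5), full_eap = c(0.4, -0.4))
  cmp <- compare_cat_full_length(pairs)
  expect_identical(cmp$n_pairs, 2L)
  expect_equal(cmp$mean_error, 0)
  expect_equal(cmp$mae, 0.1)
  expect_equal(cmp$rmse, 0.1)

  ident <- data.frame(cat_eap = c(1, 1), full_eap = c(1, 1))
  ci <- compare_cat_full_length(ident)
  expect_equal(ci$mean_error, 0)
  expect_true(is.na(ci$correlation))  # undefined, flagged as NA

  expect_error(compare_cat_full_length(pairs[0, ]), "no same-day")

  # end-to-end: paired same-day records from a small study
  bank <- simulate_item_bank()
  cohort <- simulate_cohort(c(daily = 2), c(daily = 1), weeks = 2,
                            seed = 3)
  study <- run_study(cohort, bank, full_length_weeks = c(0, 2), seed = 8)
  cmp2 <- compare_cat_full_length(study)
  expect_identical(cmp2$n_pairs, 4L)  # 2 respondents x 2 full-length days
  expect_lt(cmp2$rmse, 1)
})
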