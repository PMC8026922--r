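test_that("per-1000 normalisation is plain arithmetic with guarded input", {
  expect_equal(per1000(0, 500), 0)
  expect_equal(per1000(50, 1000), 50)
  expect_equal(per1000(7, 2000), 3.5)
  expect_error(per1000(1, 0), "positive")
})

test_that("LYG is the paired difference of death ages per 1000", {
  person <- data.frame(eligible = c(1, 1, 0, 1),
                       death_age = c(80, 90, 70, 75),
                       death_age_unscreened = c(80, 80, 50, 75))
  expect_equal(lyg(person), 10 / 3 * 1000)
  same <- transform(person, death_age = death_age_unscreened)
  expect_equal(lyg(same), 0)
  expect_error(lyg(data.frame(eligible = 1, death_age = 80)), "paired")
})

test_that("screening that can never detect leaves outcomes unchanged", {
  arms0 <- list(screening = c(0, 0, 0), followup = c(0, 0, 0))
  sim <- simulate_cohort(3000, seed = 9, strat = strategy("FIT"),
                         arms = arms0, stool = silent_stool("FIT"),
                         col = colonoscopy_profile(specificity = 1))
  expect_equal(lyg(sim$person), 0)
  expect_equal(sim$person$death_age, sim$person$death_age_unscreened)
  red <- reductions(sim$person)
  expect_equal(red$incidence_reduction_pct, 0)
  expect_equal(red$mortality_reduction_pct, 0)
})

test_that("incidence and mortality reductions follow their definitions", {
  person <- data.frame(
    eligible = rep(1, 100),
    dx_age = c(rep(60, 20), rep(NA, 80)),
    dx_age_unscreened = c(rep(60, 100)),
    death_age = c(rep(65, 10), rep(80, 90)),
    death_age_unscreened = c(rep(65, 50), rep(80, 50)),
    other_cause_death_age = rep(80, 100))
  red <- reductions(person)
  expect_equal(red$incidence_reduction_pct, 80)
  expect_equal(red$mortality_reduction_pct, 100 * (1 - 10 / 50))
  none <- transform(person, dx_age_unscreened = NA_real_,
                    death_age_unscreened = other_cause_death_age)
  expect_true(is.na(reductions(none)$incidence_reduction_pct))
})

test_that("weighted AMR pools cross-sections with exam-count weights", {
  amr <- data.frame(age = c(55, 60), exams = c(10, 30),
                    present = c(2, 1), missed = c(1, 0))
  expect_equal(weighted_amr(amr), (0.5 * 10 + 0 * 30) / 40 * 100)
  # single exam missing 1 of 2
  expect_equal(weighted_amr(data.frame(age = 60, exams = 1, present = 2,
                                       missed = 1)), 50)
  # perfect detection
  expect_equal(weighted_amr(data.frame(age = 60, exams = 5, present = 3,
                                       missed = 0)), 0)
  expect_true(is.na(weighted_amr(data.frame(age = 60, exams = 4,
                                            present = 0, missed = 0))))
  # bounds: between min and max cross-sectional AMR
  amr2 <- data.frame(age = 1:5, exams = c(3, 7, 2, 9, 4),
                     present = c(10, 8, 5, 9, 12),
                     missed = c(2, 1, 4, 0, 6))
  w <- weighted_amr(amr2)
  cross <- 100 * amr2$missed / amr2$present
  expect_gte(w, min(cross))
  expect_lte(w, max(cross))
})

test_that("ADR counts first follow-up colonoscopies with a detection", {
  person <- data.frame(eligible = rep(1, 10),
                       first_followup_detected = c(rep(1, 3), rep(0, 7)),
                       first_followup_age = rep(58, 10))
  r <- adr_first_followup(person)
  expect_equal(r$adr_pct, 30)
  expect_equal(r$mean_age, 58)
  empty <- data.frame(eligible = 1, first_followup_detected = NA,
                      first_followup_age = NA)
  expect_true(is.na(adr_first_followup(empty)$adr_pct))
})

test_that("ADR on a constructed-prevalence cohort matches p times s", {
  # 40% of individuals carry exactly one small adenoma; every stool test
  # is positive (specificity 0); small-adenoma sensitivity 0.75
  n <- 8000
  prof <- test_profile("FIT", sens_crc = 0, sens_advanced_adenoma = 0,
                       sens_nonadvanced_adenoma = 1, specificity = 0)
  arms <- list(screening = c(0.75, 0, 0), followup = c(0.75, 0, 0))
  st <- strategy("FIT", start_age = 50, stop_age = 51)
  det <- logical(n)
  for (i in seq_len(n)) {
    les <- if (i %% 5 < 2) {          # deterministic 40% prevalence
      data.frame(onset_age = 49, time_to_10mm = 60)
    } else NULL
    h <- scripted_history(les, other_cause_death_age = 90, id = i)
    r <- run_strategy(h, st, arms, stool = prof,
                      col = colonoscopy_profile(specificity = 1))
    det[i] <- isTRUE(r$first_followup_detected)
  }
  p_exp <- 0.4 * 0.75
  expect_lt(abs(mean(det) - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("percent LYG versus colonoscopy reproduces the reported ratios", {
  expect_equal(pct_lyg_vs_colonoscopy(100, 100), 100)
  expect_equal(round(pct_lyg_vs_colonoscopy(317.8, 351.9), 1), 90.3)
  expect_equal(round(pct_lyg_vs_colonoscopy(299.5, 351.9), 1), 85.1)
  expect_true(is.na(pct_lyg_vs_colonoscopy(100, 0)))
})

test_that("outcome_table aggregates a small simulated cell coherently", {
  arms <- scenario_arms(build_scenarios(), 1)
  sim <- simulate_cohort(5000, seed = 27, strat = strategy("mt-sDNA"),
                         arms = arms)
  ot <- outcome_table(sim, "mt-sDNA", 1L)
  expect_equal(nrow(ot), 1L)
  expect_true(ot$crc_cases <= ot$crc_cases_unscreened)
  expect_true(ot$crc_deaths <= ot$crc_deaths_unscreened)
  expect_true(ot$weighted_amr_pct >= 0 && ot$weighted_amr_pct <= 100)
  expect_true(ot$adr_first_followup_pct >= 0 &&
                ot$adr_first_followup_pct <= 100)
  expect_gt(ot$stool_tests, 0)
  expect_gt(ot$lyg, 0)
})
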