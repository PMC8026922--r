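test_that("lesion-free schedules give 26 FIT, 9 mt-sDNA, 3 colonoscopy exams", {
  h <- scripted_history(NULL, other_cause_death_age = 90, id = 1)
  arms <- scenario_arms(build_scenarios(), 1)
  fit <- run_strategy(h, strategy("FIT"), arms, stool = silent_stool("FIT"))
  expect_equal(fit$n_stool_tests, 26L)
  expect_equal(fit$n_colonoscopies, 0L)
  sdna <- run_strategy(h, strategy("mt-sDNA"), arms,
                       stool = silent_stool("mt-sDNA"))
  expect_equal(sdna$n_stool_tests, 9L)
  expect_equal(sort(sdna$events$age[sdna$events$event == "stool_test"]),
               seq(50, 74, by = 3))
  # colonoscopy strategy with certain-negative findings: 50, 60, 70
  col <- run_strategy(h, strategy("colonoscopy"), arms,
                      col = colonoscopy_profile(specificity = 1,
                                                full_reach_prob = 1))
  expect_equal(col$n_colonoscopies, 3L)
  expect_equal(col$events$age[col$events$event == "colonoscopy"],
               c(50, 60, 70))
})

test_that("stool test follows the per-person lesion hierarchy", {
  # no lesions + perfect specificity: always negative
  h0 <- scripted_history(NULL, other_cause_death_age = 90, id = 2)
  expect_false(stool_test(h0, 60, silent_stool("FIT"))$positive)
  # preclinical CRC with sensitivity 1: always positive
  hc <- scripted_history(
    data.frame(onset_age = 45, time_to_10mm = 6, transition_age = 55,
               clinical_age = 64),
    other_cause_death_age = 90, id = 3)
  prof <- test_profile("FIT", sens_crc = 1)
  r <- stool_test(hc, 60, prof)
  expect_true(r$positive)
  expect_equal(r$category, "crc")
  # a large adenoma routes through the advanced stratum
  ha <- scripted_history(data.frame(onset_age = 45, time_to_10mm = 6),
                         other_cause_death_age = 90, id = 4)
  r2 <- stool_test(ha, 60, test_profile("FIT"))
  expect_equal(r2$prob, 0.238)
  r3 <- stool_test(ha, 46, test_profile("FIT"))   # still small at 46
  expect_equal(r3$prob, 0.076)
})

test_that("stool false-positive rate matches 1 - specificity", {
  # lesion-free cohort under mt-sDNA: every colonoscopy session marks one
  # positive test, so the session/test ratio estimates 1 - 0.898
  arms <- scenario_arms(build_scenarios(), 1)
  sim <- simulate_cohort(17000, seed = 21, strat = strategy("mt-sDNA"),
                         arms = arms, params = no_lesion_params(),
                         col = colonoscopy_profile(full_reach_prob = 1))
  tests <- sum(sim$person$n_stool_tests)
  positives <- sum(sim$person$n_colonoscopies)
  expect_gt(tests, 1e5)
  p_hat <- positives / tests
  expect_lt(abs(p_hat - 0.102), 3 * sqrt(0.102 * 0.898 / tests))
})

test_that("per-lesion colonoscopy detection matches the configured arm", {
  profile <- colonoscopy_profile()
  n <- 2e4
  det_scr <- logical(n); det_fu <- logical(n)
  arms10 <- scenario_arms(build_scenarios(), 10)
  for (i in seq_len(n)) {
    h <- scripted_history(data.frame(onset_age = 48, time_to_10mm = 6),
                          other_cause_death_age = 90, id = i)
    # 12 mm at age 54.6; use 55 -> large
    det_scr[i] <- colonoscopy(h, 55, arms10$screening, profile,
                              seed = 2)$n_detected == 1
    det_fu[i] <- colonoscopy(h, 55, arms10$followup, profile,
                             seed = 2)$n_detected == 1
  }
  p_s <- unname(arms10$screening["large"])   # 0.875
  p_f <- unname(arms10$followup["large"])    # 0.981
  expect_lt(abs(mean(det_scr) - p_s), 3 * sqrt(p_s * (1 - p_s) / n))
  expect_lt(abs(mean(det_fu) - p_f), 3 * sqrt(p_f * (1 - p_f) / n))
  # paired replicates: the arm gap is the sensitivity gap (~10.6 pp)
  expect_true(all(det_fu | !det_scr))        # monotone coupling
  expect_lt(abs(mean(det_fu) - mean(det_scr) - (p_f - p_s)),
            3 * sqrt(0.106 * 0.894 / n))
})

test_that("all-zero sensitivity and perfect specificity leave truth untouched", {
  h <- scripted_history(data.frame(onset_age = c(48, 52),
                                   time_to_10mm = c(6, 10)),
                        other_cause_death_age = 90, id = 5)
  r <- colonoscopy(h, 60, c(0, 0, 0),
                   colonoscopy_profile(specificity = 1), seed = 1)
  expect_equal(r$n_detected, 0L)
  expect_false(any(r$removed))
  expect_equal(r$n_present, 2L)
  expect_equal(r$n_missed, 2L)
  expect_false(r$fp_polypectomy)
})

test_that("surveillance policy maps findings to the documented intervals", {
  pol <- surveillance_policy()
  expect_true(surveillance_interval(0, 0, pol)$exit)
  expect_equal(surveillance_interval(0, 0, pol)$years, 10)
  expect_equal(surveillance_interval(1, 12, pol)$years, 3)
  expect_equal(surveillance_interval(3, 4, pol)$years, 3)
  expect_equal(surveillance_interval(2, 4, pol)$years, 5)
  expect_false(surveillance_interval(1, 4, pol)$exit)
})

test_that("every positive stool test triggers one follow-up colonoscopy", {
  arms <- scenario_arms(build_scenarios(), 5)
  coh <- sample_cohort(150, seed = 31)
  params <- nh_params()
  for (i in seq_len(150)) {
    h <- sample_disease_history(coh[i, ], params, 31)
    r <- run_strategy(h, strategy("FIT"), arms, params = params, seed = 31)
    ev <- r$events
    pos_ages <- ev$age[ev$event == "stool_test" & ev$positive]
    fu_ages <- ev$age[ev$event == "colonoscopy" & ev$indication == "followup"]
    expect_equal(sort(pos_ages), sort(fu_ages))
    # no events after death
    expect_true(all(ev$age <= r$death_age))
  }
})

test_that("negative follow-up returns to stool testing 10 years later", {
  # one small adenoma guaranteed positive test at 50, missed at colonoscopy
  h <- scripted_history(data.frame(onset_age = 49, time_to_10mm = 50),
                        other_cause_death_age = 90, id = 6)
  prof <- test_profile("FIT", sens_nonadvanced_adenoma = 1, specificity = 1)
  arms0 <- list(screening = c(0, 0, 0), followup = c(0, 0, 0))
  r <- run_strategy(h, strategy("FIT"), arms0, stool = prof,
                    col = colonoscopy_profile(specificity = 1))
  ages <- r$events$age[r$events$event == "stool_test"]
  # positive at 50, colonoscopy negative, next stool at 60, ... at 70
  expect_equal(ages[1:2], c(50, 60))
  expect_equal(r$events$age[r$events$event == "colonoscopy"][1], 50)
})

test_that("positive findings schedule surveillance by the policy interval", {
  # large adenoma detected at 50 -> surveillance at 53, 56, ... while the
  # lesion history stays positive-free afterwards
  h <- scripted_history(data.frame(onset_age = 44, time_to_10mm = 6),
                        other_cause_death_age = 90, id = 7)
  prof <- test_profile("FIT", sens_advanced_adenoma = 1, specificity = 1)
  arms1 <- list(screening = c(1, 1, 1), followup = c(1, 1, 1))
  r <- run_strategy(h, strategy("FIT"), arms1, stool = prof,
                    col = colonoscopy_profile(specificity = 1,
                                              full_reach_prob = 1))
  ev <- r$events
  col_ages <- ev$age[ev$event == "colonoscopy"]
  expect_equal(col_ages[1:2], c(50, 53))
  expect_equal(ev$indication[ev$event == "colonoscopy"][2], "surveillance")
  # the surveillance exam finds nothing (lesion removed) and exits
  expect_equal(ev$n_detected[ev$event == "colonoscopy"], c(1, 0))
  # back on stool testing at 63
  expect_true(63 %in% ev$age[ev$event == "stool_test"])
})

test_that("scenario 1 outcomes are invariant to the arm-assignment flag", {
  arms <- scenario_arms(build_scenarios(), 1)
  a <- simulate_cohort(4000, seed = 17, strat = strategy("FIT"),
                       arms = arms, fit_screening_arm = FALSE)
  b <- simulate_cohort(4000, seed = 17, strat = strategy("FIT"),
                       arms = arms, fit_screening_arm = TRUE)
  expect_identical(a$person, b$person)
  expect_identical(a$amr, b$amr)
})

test_that("raising sensitivity never loses detections nor adds cancers", {
  lo <- list(screening = c(0.5, 0.5, 0.5), followup = c(0.5, 0.5, 0.5))
  hi <- list(screening = c(0.9, 0.9, 0.9), followup = c(0.9, 0.9, 0.9))
  a <- simulate_cohort(5000, seed = 23, strat = strategy("colonoscopy"),
                       arms = lo)$person
  b <- simulate_cohort(5000, seed = 23, strat = strategy("colonoscopy"),
                       arms = hi)$person
  expect_gte(sum(b$n_adenomas_removed), sum(a$n_adenomas_removed))
  expect_lte(sum(!is.na(b$dx_age)), sum(!is.na(a$dx_age)))
})

test_that("engine and R reference agree person by person", {
  tab <- build_scenarios()
  arms <- scenario_arms(tab, 8)
  params <- nh_params()
  coh <- sample_cohort(120, seed = 11)
  for (st_name in c("colonoscopy", "FIT", "mt-sDNA")) {
    st <- strategy(st_name)
    pe <- simulate_cohort(120, seed = 11, strat = st, arms = arms)$person
    for (i in seq_len(120)) {
      h <- sample_disease_history(coh[i, ], params, 11)
      r <- run_strategy(h, st, arms, params = params, seed = 11)
      expect_equal(r$death_age, pe$death_age[i])
      expect_equal(r$dx_age, pe$dx_age[i])
      expect_identical(r$n_colonoscopies, pe$n_colonoscopies[i])
      expect_identical(r$n_stool_tests, pe$n_stool_tests[i])
      expect_identical(r$n_complications, pe$n_complications[i])
      expect_equal(r$first_followup_age, pe$first_followup_age[i])
    }
  }
})
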