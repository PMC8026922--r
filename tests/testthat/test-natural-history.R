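test_that("adenoma counts follow the Poisson closed form", {
  # constant intensity 0.02/yr over 50 years, frailty 1 -> Poisson(1.0)
  p <- flat_onset_params(rate = 0.02, to = 50)
  sim <- simulate_cohort(1e5, seed = 3, params = p)
  m <- mean(sim$person$n_adenomas)
  expect_lt(abs(m - 1.0), 0.01)
  expect_lt(abs(stats::var(sim$person$n_adenomas) - 1.0), 0.03)
  # all onsets inside the window where intensity is positive
  les <- cpp_lesions(3, 1:2000, crcscreen:::engine_nh_config(
    p, default_life_table()))
  expect_true(all(les$onset_age <= 50))
})

test_that("zero intensity yields no adenomas and no CRC", {
  sim <- simulate_cohort(2000, seed = 1, params = no_lesion_params())
  expect_true(all(sim$person$n_adenomas == 0))
  expect_true(all(is.na(sim$person$dx_age_unscreened)))
})

test_that("doubling frailty doubles the expected count under paired seeds", {
  p1 <- flat_onset_params(rate = 0.02, to = 50)
  p2 <- flat_onset_params(rate = 0.02, to = 50)
  p2$frailty <- list(meanlog = log(2), sdlog = 0)
  n1 <- simulate_cohort(5e4, seed = 11, params = p1)$person$n_adenomas
  n2 <- simulate_cohort(5e4, seed = 11, params = p2)$person$n_adenomas
  expect_true(all(n2 >= n1))            # same uniforms, higher intensity
  expect_lt(abs(mean(n2) / mean(n1) - 2), 0.05)
})

test_that("growth curve hits its boundary conditions and is monotone", {
  expect_equal(adenoma_diameter(55, 55, 8), 1)
  expect_equal(adenoma_diameter(63, 55, 8), 10)
  mid <- adenoma_diameter(seq(55.1, 62.9, by = 0.2), 55, 8)
  expect_true(all(mid > 1 & mid < 10))
  expect_true(all(diff(mid) > 0))
  expect_error(adenoma_diameter(54, 55, 8), ">=")
})

test_that("transformation times follow the integrated size-dependent hazard", {
  params <- nh_params()
  ind <- list(id = 1L)
  # zero hazard: never transforms
  p0 <- nh_params(transition = list(rate_at_10mm = 0, size_power = 3))
  expect_equal(sample_transition(ind, 1, 50, 10, p0, 1), Inf)

  # near-size-independent hazard ~ exponential(rate) in time
  pc <- nh_params(transition = list(rate_at_10mm = 0.05, size_power = 1e-8))
  E <- -log(hash_u01(1, 1:1e5, 7, 1, 0))
  tt <- vapply(E, crcscreen:::transition_time_from_E, 0, t10 = 12,
               params = pc)
  finite <- is.finite(tt)
  # censor both sides at 150 (the engine's horizon) for the comparison
  expect_lt(abs(mean(pmin(tt[finite], 150)) - 20), 3 * 20 / sqrt(1e5) + 0.1)
  expect_lt(abs(mean(tt[finite] <= 10) - (1 - exp(-0.5))),
            3 * sqrt(0.4 * 0.6 / 1e5) + 1e-3)

  # hazard increases with diameter: faster-growing lesions transform sooner
  t_fast <- crcscreen:::transition_time_from_E(0.05, 5, params)
  t_slow <- crcscreen:::transition_time_from_E(0.05, 25, params)
  expect_lt(t_fast, t_slow)
})

test_that("removed lesions never transform afterwards", {
  # a lesion removed before its transformation age yields no CRC
  h <- scripted_history(
    data.frame(onset_age = 48, time_to_10mm = 6, transition_age = 60,
               clinical_age = 63),
    other_cause_death_age = 90, id = 21)
  arms <- list(screening = c(1, 1, 1), followup = c(1, 1, 1))
  r <- run_strategy(h, strategy("colonoscopy"), arms, seed = 1)
  expect_equal(r$dx_mode, "none")
  expect_equal(r$death_age, 90)
  expect_equal(sum(r$events$event == "colonoscopy" &
                     r$events$n_detected == 1), 1L)
})

test_that("degenerate sojourn shifts clinical onset by its point mass", {
  p <- nh_params(sojourn = list(meanlog = log(3), sdlog = 0))
  s <- sample_sojourn_and_stage(list(id = 5L), 1, transition_age = 60,
                                params = p, seed = 1)
  expect_equal(s$sojourn, 3.0)
  expect_equal(s$clinical_age, 63.0)
})

test_that("stage draws follow the configured distribution", {
  u <- hash_u01(2, 1:1e5, 9, 1, 0)
  st <- vapply(u, crcscreen:::stage_from_u_r, 1L,
               probs = c(0.25, 0.25, 0.25, 0.25))
  freq <- tabulate(st, 4) / 1e5
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 1e5)))
  # same uniform maps to an earlier or equal stage under the screen shift
  p <- nh_params()
  st_sympt <- vapply(u[1:2e4], crcscreen:::stage_from_u_r, 1L,
                     probs = p$stage_symptomatic)
  st_scr <- vapply(u[1:2e4], crcscreen:::stage_from_u_r, 1L,
                   probs = p$stage_screen)
  expect_true(all(st_scr <= st_sympt))
})

test_that("survival is a stage-monotone cure/exponential mixture", {
  p <- nh_params(survival_cure = c(1, 0.5, 0.2, 0),
                 survival_mean = c(10, 7, 4, 1.5))
  ind <- list(id = 9L)
  expect_equal(crc_survival(ind, 1, 1, 60, p, 1), Inf)  # cure fraction 1
  # exponential mean for a never-cured stage
  p4 <- nh_params(survival_cure = c(0, 0, 0, 0),
                  survival_mean = c(10, 7, 4, 2))
  res <- vapply(1:2e4, function(id)
    crc_survival(list(id = id), 1, 4, 0, p4, 3), 0)
  expect_lt(abs(mean(res) - 2), 3 * 2 / sqrt(2e4))
  # paired draws: later stage never outlives earlier stage
  s1 <- vapply(1:2000, function(id)
    crc_survival(list(id = id), 1, 1, 0, nh_params(), 3), 0)
  s4 <- vapply(1:2000, function(id)
    crc_survival(list(id = id), 1, 4, 0, nh_params(), 3), 0)
  expect_true(all(s4 <= s1))
  expect_error(crc_survival(ind, 1, 5, 60, p, 1))
})

test_that("conservation and limiting behaviour of the natural course", {
  sim <- simulate_cohort(2e4, seed = 5)
  pe <- sim$person[sim$person$eligible == 1, ]
  cases <- sum(!is.na(pe$dx_age_unscreened))
  deaths <- sum(pe$death_age_unscreened < pe$other_cause_death_age)
  expect_lte(deaths, cases)
  expect_lte(cases, nrow(pe))
  expect_true(all(pe$death_age_unscreened <= pe$other_cause_death_age))

  # infinite sojourn: adenoma prevalence unchanged, CRC disappears
  p_inf <- nh_params(sojourn = list(meanlog = 20, sdlog = 0.01))
  sim2 <- simulate_cohort(2e4, seed = 5, params = p_inf)
  expect_equal(sim2$person$n_adenomas, sim$person$n_adenomas)
  expect_equal(sum(!is.na(sim2$person$dx_age_unscreened)), 0L)
})

test_that("natural course is reproducible and matches the R reference", {
  a <- simulate_cohort(500, seed = 13)$person
  b <- simulate_cohort(500, seed = 13)$person
  expect_identical(a, b)
  coh <- sample_cohort(60, seed = 13)
  params <- nh_params()
  for (i in seq_len(60)) {
    h <- sample_disease_history(coh[i, ], params, 13)
    nc <- natural_course(h, params, 13)
    expect_equal(nc$death_age, a$death_age_unscreened[i])
    expect_equal(nc$dx_age, a$dx_age_unscreened[i])
    expect_equal(nc$eligible, a$eligible[i] == 1)
  }
})
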