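# Screening overlay: stool tests, colonoscopies with indication-specific
# adenoma sensitivity, follow-up and surveillance scheduling, complications.
#
# `run_strategy()` is the per-person reference implementation with a full
# event log; `simulate_cohort()` drives the C++ engine over whole cohorts.
# Both consume identical hashed substreams, and the test suite checks that
# they agree person by person.

#' Stool-test performance profile
#'
#' Defaults are per-person sensitivities and specificity for FIT (annual)
#' and mt-sDNA (triennial): CRC 73.8/92.3%, advanced adenoma (>= 10 mm)
#' 23.8/42.4%, non-advanced adenoma 7.6/17.2%, specificity 96.4/89.8%. The
#' advanced-adenoma value is used as a proxy for lesions >= 10 mm and the
#' non-advanced value for 1-9 mm. For alternate input sets the profile also
#' accepts a full size-class x location sensitivity matrix and an age-based
#' specificity schedule.
#'
#' @param name "FIT" or "mt-sDNA".
#' @param sens_crc per-person sensitivity for preclinical CRC; scalar or
#'   length-4 by location (rectum, distal, proximal, cecum).
#' @param sens_advanced_adenoma,sens_nonadvanced_adenoma per-person
#'   sensitivities by the advanced (>= 10 mm) / non-advanced split.
#' @param sens_adenoma optional 3 x 4 matrix (size class small/medium/large
#'   by location) overriding the advanced/non-advanced split.
#' @param specificity scalar specificity, or a numeric vector indexed by
#'   single year of age 0..100 (length 101).
#' @param interval_years screening interval.
#' @return list of class `test_profile`.
#' @export
test_profile <- function(name = c("FIT", "mt-sDNA"),
                         sens_crc = NULL,
                         sens_advanced_adenoma = NULL,
                         sens_nonadvanced_adenoma = NULL,
                         sens_adenoma = NULL,
                         specificity = NULL,
                         interval_years = NULL) {
  name <- match.arg(name)
  def <- if (name == "FIT") {
    list(crc = 0.738, adv = 0.238, nonadv = 0.076, spec = 0.964, int = 1)
  } else {
    list(crc = 0.923, adv = 0.424, nonadv = 0.172, spec = 0.898, int = 3)
  }
  if (is.null(sens_crc)) sens_crc <- def$crc
  if (is.null(sens_advanced_adenoma)) sens_advanced_adenoma <- def$adv
  if (is.null(sens_nonadvanced_adenoma)) sens_nonadvanced_adenoma <- def$nonadv
  if (is.null(specificity)) specificity <- def$spec
  if (is.null(interval_years)) interval_years <- def$int
  if (is.null(sens_adenoma)) {
    sens_adenoma <- matrix(c(rep(sens_nonadvanced_adenoma, 4),
                             rep(sens_nonadvanced_adenoma, 4),
                             rep(sens_advanced_adenoma, 4)),
                           nrow = 3, byrow = TRUE)
  }
  sens_adenoma <- as.matrix(sens_adenoma)
  if (!all(dim(sens_adenoma) == c(3, 4)))
    stop("`sens_adenoma` must be a 3 x 4 (size class x location) matrix")
  if (length(sens_crc) == 1) sens_crc <- rep(sens_crc, 4)
  if (length(specificity) == 1) specificity <- rep(specificity, 101)
  if (length(specificity) != 101)
    stop("`specificity` must be scalar or length 101 (ages 0..100)")
  probs <- c(sens_crc, sens_adenoma, specificity)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(name = name, sens_crc = sens_crc,
                 sens_adenoma = sens_adenoma, specificity = specificity,
                 interval_years = interval_years),
            class = "test_profile")
}

#' Colonoscopy performance profile (per lesion)
#'
#' @param sens_crc_within_reach per-lesion sensitivity for preclinical CRC.
#' @param specificity 1 minus the probability that an exam without detected
#'   adenomas still leads to an unnecessary (non-adenomatous) polypectomy.
#' @param full_reach_prob probability that the exam reaches the cecum; a
#'   partial-reach exam is immediately repeated to completion and both
#'   exams are counted.
#' @param complication list (`base`, `slope`, `ref_age`): per-exam
#'   complication probability `base * exp(slope * (age - ref_age))` applied
#'   when a polypectomy occurred.
#' @return list of class `colonoscopy_profile`.
#' @export
colonoscopy_profile <- function(sens_crc_within_reach = 0.95,
                                specificity = 0.86,
                                full_reach_prob = 0.95,
                                complication = list(base = 0.0025,
                                                    slope = 0.05,
                                                    ref_age = 65)) {
  structure(list(sens_crc_within_reach = sens_crc_within_reach,
                 specificity = specificity,
                 full_reach_prob = full_reach_prob,
                 complication = complication),
            class = "colonoscopy_profile")
}

#' Screening strategy
#'
#' @param modality "colonoscopy", "FIT" or "mt-sDNA".
#' @param start_age,stop_age screening era (exams at integer ages
#'   `start_age, start_age + interval, ... <= stop_age`).
#' @param interval years between routine exams; defaults 10 / 1 / 3 by
#'   modality.
#' @param adherence fixed at 1 (100% adherence is a model assumption).
#' @return list of class `strategy`.
#' @export
strategy <- function(modality = c("colonoscopy", "FIT", "mt-sDNA"),
                     start_age = 50, stop_age = 75, interval = NULL,
                     adherence = 1) {
  modality <- match.arg(modality)
  if (is.null(interval))
    interval <- c(colonoscopy = 10, FIT = 1, `mt-sDNA` = 3)[[modality]]
  stopifnot(start_age < stop_age, interval >= 1)
  if (adherence != 1) stop("only 100% adherence is modeled")
  structure(list(modality = modality, start_age = start_age,
                 stop_age = stop_age, interval = interval,
                 adherence = adherence),
            class = "strategy")
}

#' Surveillance policy after a positive colonoscopy
#'
#' Default mapping (US multi-society style, replaceable): at least one
#' adenoma of 10 mm or more, or 3 or more adenomas removed -> repeat in 3
#' years; 1-2 smaller
#' adenomas -> 5 years; no adenomas found -> exit surveillance, with the
#' next routine screen due `return_interval` (10) years later. Surveillance
#' exams are scheduled while the next exam age is at most `stop_age` (85).
#'
#' @param count_threshold,size_threshold_mm findings triggering the short
#'   interval.
#' @param interval_large,interval_small surveillance intervals (years).
#' @param return_interval years until the next routine screen after a
#'   negative colonoscopy.
#' @param stop_age last age at which a surveillance exam may be scheduled.
#' @return list of class `surveillance_policy`.
#' @export
surveillance_policy <- function(count_threshold = 3, size_threshold_mm = 10,
                                interval_large = 3, interval_small = 5,
                                return_interval = 10, stop_age = 85) {
  stopifnot(interval_large > 0, interval_small > 0, return_interval > 0)
  structure(list(count_threshold = count_threshold,
                 size_threshold_mm = size_threshold_mm,
                 interval_large = interval_large,
                 interval_small = interval_small,
                 return_interval = return_interval,
                 stop_age = stop_age),
            class = "surveillance_policy")
}

#' Next interval implied by colonoscopy findings
#'
#' @param n_detected number of adenomas detected (and removed).
#' @param max_size_mm largest removed adenoma (mm); ignored when
#'   `n_detected` is 0.
#' @param policy a [surveillance_policy()].
#' @return list: `exit` (logical; `TRUE` means return to routine screening)
#'   and `years` until the next exam.
#' @export
surveillance_interval <- function(n_detected, max_size_mm = 0,
                                  policy = surveillance_policy()) {
  stopifnot(n_detected >= 0)
  if (n_detected == 0)
    return(list(exit = TRUE, years = policy$return_interval))
  years <- if (n_detected >= policy$count_threshold ||
               max_size_mm >= policy$size_threshold_mm)
    policy$interval_large else policy$interval_small
  list(exit = FALSE, years = years)
}

# lesion status helpers -----------------------------------------------------

# diameters and status of lesions at an exam age given removal flags
lesion_status <- function(les, age, removed) {
  active <- !removed & les$onset_age <= age
  is_aden <- active & les$transition_age > age
  is_crc <- active & les$transition_age <= age
  d <- rep(NA_real_, nrow(les))
  d[active] <- adenoma_diameter(age, les$onset_age[active],
                                les$time_to_10mm[active])
  list(is_aden = is_aden, is_crc = is_crc, diameter = d)
}

#' Apply a stool test to the latent truth at an exam age
#'
#' Per-person hierarchy: if a preclinical cancer is present the positivity
#' probability is the CRC sensitivity (of the first such lesion's
#' location); otherwise the most advanced (largest) adenoma sets it through
#' the size-class x location sensitivity table; with no lesion the test is
#' positive with probability 1 - specificity(age).
#'
#' @param history `disease_history`.
#' @param age integer exam age.
#' @param profile [test_profile()].
#' @param seed master seed.
#' @param removed logical vector of already-removed lesions.
#' @return list: `positive`, `prob`, and the triggering category
#'   (`"crc"`, `"adenoma"`, `"none"`).
#' @export
stool_test <- function(history, age, profile, seed = 1,
                       removed = rep(FALSE, nrow(history$lesions))) {
  st <- lesion_status(history$lesions, age, removed)
  if (any(st$is_crc)) {
    i <- which(st$is_crc)[1]
    prob <- profile$sens_crc[history$lesions$segment[i]]
    cat_ <- "crc"
  } else if (any(st$is_aden)) {
    d <- st$diameter
    d[!st$is_aden] <- -Inf
    i <- which.max(d)
    cls <- match(size_class_of(d[i]), c("small", "medium", "large"))
    prob <- profile$sens_adenoma[cls, history$lesions$segment[i]]
    cat_ <- "adenoma"
  } else {
    prob <- 1 - profile$specificity[min(age, 100) + 1]
    cat_ <- "none"
  }
  u <- hash_u01(seed, history$id, .P$stool, age, 0)
  list(positive = u < prob, prob = prob, category = cat_)
}

#' Perform one colonoscopy session
#'
#' Samples reach (a partial-reach exam is immediately repeated to
#' completion; both exams count), detects each in-reach adenoma
#' independently with the arm- and size-specific sensitivity, removes
#' detections, detects preclinical CRC with the per-lesion CRC sensitivity,
#' draws the unnecessary-polypectomy event (1 - specificity) and the
#' age-dependent complication.
#'
#' @param history `disease_history`.
#' @param age integer exam age.
#' @param sens length-3 adenoma sensitivity (small, medium, large) of the
#'   exam's arm.
#' @param profile [colonoscopy_profile()].
#' @param seed master seed.
#' @param removed logical vector of already-removed lesions.
#' @return list: updated `removed`, `n_present`, `n_detected`, `n_missed`,
#'   `max_size_mm`, `cancer_lesion` (lesion key or NA), `n_exams` (1, or 2
#'   after a partial first reach), `fp_polypectomy`, `complication`.
#' @export
colonoscopy <- function(history, age, sens, profile = colonoscopy_profile(),
                        seed = 1,
                        removed = rep(FALSE, nrow(history$lesions))) {
  les <- history$lesions
  id <- history$id
  st <- lesion_status(les, age, removed)
  full <- hash_u01(seed, id, .P$reach, age, 0) < profile$full_reach_prob
  n_det <- 0L; max_d <- 0; cancer <- NA_integer_
  for (i in seq_len(nrow(les))) {
    if (!(st$is_aden[i] || st$is_crc[i])) next
    u <- hash_u01(seed, id, .P$detect, les$lesion[i], age)
    if (st$is_aden[i]) {
      cls <- match(size_class_of(st$diameter[i]),
                   c("small", "medium", "large"))
      if (u < sens[cls]) {
        removed[i] <- TRUE
        n_det <- n_det + 1L
        max_d <- max(max_d, st$diameter[i])
      }
    } else if (u < profile$sens_crc_within_reach && is.na(cancer)) {
      cancer <- les$lesion[i]
    }
  }
  fp <- hash_u01(seed, id, .P$fp, age, 0) < (1 - profile$specificity)
  polyp <- n_det > 0L || fp
  risk <- min(1, profile$complication$base *
                exp(profile$complication$slope *
                      (age - profile$complication$ref_age)))
  compl <- polyp && hash_u01(seed, id, .P$compl, age, 0) < risk
  list(removed = removed, n_present = sum(st$is_aden),
       n_detected = n_det, n_missed = sum(st$is_aden) - n_det,
       max_size_mm = max_d, cancer_lesion = cancer,
       n_exams = if (full) 1L else 2L,
       fp_polypectomy = fp, complication = compl)
}

#' Run a screening strategy over one disease history
#'
#' Per-person reference implementation with a dated event log. Routine
#' exams occur at integer ages `start, start + interval, ...` up to the
#' stop age under 100% adherence; a positive stool test triggers a
#' follow-up colonoscopy at the same age; positive colonoscopy findings
#' schedule surveillance by [surveillance_interval()]; symptomatic
#' presentation and other-cause death interrupt the schedule. For the
#' colonoscopy strategy, routine exams use the screening arm and
#' surveillance exams the follow-up/surveillance arm; stool strategies use
#' the follow-up/surveillance arm for every triggered colonoscopy unless
#' `fit_screening_arm` forces FIT-triggered exams onto the screening arm
#' (first sensitivity analysis).
#'
#' @param history `disease_history`.
#' @param strat [strategy()].
#' @param arms list with `screening` and `followup` length-3 adenoma
#'   sensitivities, e.g. from [scenario_arms()].
#' @param policy [surveillance_policy()].
#' @param stool [test_profile()] (for stool modalities).
#' @param col [colonoscopy_profile()].
#' @param params [nh_params()] (stage and survival at diagnosis).
#' @param seed master seed.
#' @param fit_screening_arm flag of the first sensitivity analysis.
#' @return object of class `screened_history`: `events` data.frame plus
#'   diagnosis/death summary and resource counts.
#' @export
run_strategy <- function(history, strat, arms, policy = surveillance_policy(),
                         stool = test_profile(
                           if (strat$modality == "mt-sDNA") "mt-sDNA" else "FIT"),
                         col = colonoscopy_profile(),
                         params = nh_params(), seed = 1,
                         fit_screening_arm = FALSE) {
  les <- history$lesions
  id <- history$id
  ocd <- history$other_cause_death_age
  removed <- rep(FALSE, nrow(les))
  ev <- list()
  add_ev <- function(...) ev[[length(ev) + 1L]] <<- data.frame(...)

  dx_age <- NA_real_; dx_mode <- "none"; dx_k <- NA_integer_
  n_stool <- 0L; n_col <- 0L; n_compl <- 0L
  first_fu_age <- NA_real_; first_fu_det <- NA
  min_clin <- function() {
    cl <- les$clinical_age[!removed]
    if (length(cl) == 0) Inf else min(cl)
  }
  is_fit <- strat$modality == "FIT"
  fu_arm <- if (fit_screening_arm && is_fit) arms$screening else arms$followup

  a <- strat$start_age
  kind <- if (strat$modality == "colonoscopy") "col_screen" else "stool"
  do_session <- function(age, sens, indication) {
    r <- colonoscopy(history, age, sens, col, seed, removed)
    removed <<- r$removed
    n_col <<- n_col + r$n_exams
    if (r$complication) n_compl <<- n_compl + 1L
    add_ev(age = age, event = "colonoscopy", indication = indication,
           positive = NA, n_present = r$n_present,
           n_detected = r$n_detected, n_missed = r$n_missed,
           reach_full = r$n_exams == 1L, complication = r$complication)
    r
  }
  while (!is.na(kind)) {
    tclin <- min_clin()
    if (tclin < a && tclin < ocd) {
      dx_age <- tclin; dx_mode <- "symptomatic"
      dx_k <- les$lesion[which(!removed & les$clinical_age == tclin)[1]]
      break
    }
    if (a >= ocd) break
    if (kind == "stool") {
      n_stool <- n_stool + 1L
      r <- stool_test(history, a, stool, seed, removed)
      add_ev(age = a, event = "stool_test", indication = "screening",
             positive = r$positive, n_present = NA, n_detected = NA,
             n_missed = NA, reach_full = NA, complication = NA)
      if (r$positive) {
        s <- do_session(a, fu_arm, "followup")
        if (is.na(first_fu_det)) {
          first_fu_age <- a; first_fu_det <- s$n_detected > 0L
        }
        if (!is.na(s$cancer_lesion)) {
          dx_age <- a; dx_mode <- "screen"; dx_k <- s$cancer_lesion
          break
        }
        nx <- surveillance_interval(s$n_detected, s$max_size_mm, policy)
        if (nx$exit) {
          if (a + nx$years <= strat$stop_age) a <- a + nx$years
          else kind <- NA
        } else if (a + nx$years <= policy$stop_age) {
          a <- a + nx$years; kind <- "surveil"
        } else kind <- NA
      } else if (a + strat$interval <= strat$stop_age) {
        a <- a + strat$interval
      } else kind <- NA
    } else {
      sens <- if (kind == "col_screen") arms$screening else fu_arm
      indication <- if (kind == "col_screen") "screening" else "surveillance"
      s <- do_session(a, sens, indication)
      if (!is.na(s$cancer_lesion)) {
        dx_age <- a; dx_mode <- "screen"; dx_k <- s$cancer_lesion
        break
      }
      nx <- surveillance_interval(s$n_detected, s$max_size_mm, policy)
      if (nx$exit) {
        if (a + nx$years <= strat$stop_age) {
          a <- a + nx$years
          kind <- if (strat$modality == "colonoscopy") "col_screen" else "stool"
        } else kind <- NA
      } else if (a + nx$years <= policy$stop_age) {
        a <- a + nx$years; kind <- "surveil"
      } else kind <- NA
    }
  }
  if (dx_mode == "none") {
    tclin <- min_clin()
    if (tclin < ocd) {
      dx_age <- tclin; dx_mode <- "symptomatic"
      dx_k <- les$lesion[which(!removed & les$clinical_age == tclin)[1]]
    }
  }
  stage <- NA_integer_; crc_death <- Inf
  if (dx_mode != "none") {
    stage_probs <- if (dx_mode == "screen") params$stage_screen
                   else params$stage_symptomatic
    stage <- stage_from_u_r(hash_u01(seed, id, .P$stage, dx_k, 0),
                            stage_probs)
    crc_death <- if (!is.null(history$crc_death_age_override))
      history$crc_death_age_override
    else crc_survival(history, dx_k, stage, dx_age, params, seed)
    add_ev(age = dx_age, event = "crc_diagnosis", indication = dx_mode,
           positive = NA, n_present = NA, n_detected = NA, n_missed = NA,
           reach_full = NA, complication = NA)
  }
  death <- min(ocd, crc_death)
  add_ev(age = death, event = "death",
         indication = if (crc_death < ocd) "crc" else "other",
         positive = NA, n_present = NA, n_detected = NA, n_missed = NA,
         reach_full = NA, complication = NA)
  events <- do.call(rbind, ev)
  events <- events[order(events$age), ]
  rownames(events) <- NULL
  structure(list(id = id, events = events,
                 dx_age = dx_age, dx_mode = dx_mode, stage = stage,
                 crc_death_age = if (is.finite(crc_death)) crc_death
                                 else NA_real_,
                 death_age = death,
                 n_stool_tests = n_stool, n_colonoscopies = n_col,
                 n_complications = n_compl,
                 first_followup_age = first_fu_age,
                 first_followup_detected = first_fu_det),
            class = "screened_history")
}

#' @export
print.screened_history <- function(x, ...) {
  cat(sprintf(paste0("<screened_history> id %d: %d stool test(s), ",
                     "%d colonoscopy(ies), dx %s, death %.1f\n"),
              x$id, x$n_stool_tests, x$n_colonoscopies,
              if (x$dx_mode == "none") "none"
              else sprintf("%.1f (%s)", x$dx_age, x$dx_mode),
              x$death_age))
  invisible(x)
}

# engine config builders -----------------------------------------------------

engine_nh_config <- function(params, life_table) {
  list(onset_breaks = params$onset_breaks, onset_rates = params$onset_rates,
       max_age = params$max_age, frailty = params$frailty,
       growth = params$growth, transition = params$transition,
       sojourn = params$sojourn,
       stage_symptomatic = params$stage_symptomatic,
       stage_screen = params$stage_screen,
       survival_cure = params$survival_cure,
       survival_mean = params$survival_mean,
       segment_probs = unname(params$segment_probs),
       life_table_qx = life_table$qx)
}

engine_screen_config <- function(strat, arms, stool, col, policy,
                                 fit_screening_arm) {
  modality <- match(strat$modality, c("colonoscopy", "FIT", "mt-sDNA")) - 1L
  list(modality = modality,
       start_age = strat$start_age, stop_age = strat$stop_age,
       interval = strat$interval,
       stool_sens_crc = stool$sens_crc,
       stool_sens_adenoma = stool$sens_adenoma,
       stool_spec = stool$specificity,
       col_sens_screening = unname(arms$screening),
       col_sens_followup = unname(arms$followup),
       col_sens_crc = col$sens_crc_within_reach,
       col_spec = col$specificity,
       full_reach = col$full_reach_prob,
       compl_base = col$complication$base,
       compl_slope = col$complication$slope,
       compl_ref_age = col$complication$ref_age,
       surveillance_large = policy$interval_large,
       surveillance_small = policy$interval_small,
       surveillance_stop_age = policy$stop_age,
       return_interval = policy$return_interval,
       count_threshold = as.integer(policy$count_threshold),
       size_threshold = policy$size_threshold_mm,
       fit_screening_arm = isTRUE(fit_screening_arm))
}

#' Simulate a cohort through the fast engine
#'
#' Generates each individual's latent disease history and, when a strategy
#' is given, the screened course, in one C++ pass per person. The
#' unscreened (natural-course) outcomes are always returned, so
#' screened-versus-unscreened comparisons are paired within person by
#' construction.
#'
#' @param n cohort size (ids `1:n`), or pass `ids` explicitly.
#' @param seed master seed.
#' @param strat [strategy()] or `NULL` for the natural course only.
#' @param arms sensitivity arms from [scenario_arms()] (required with a
#'   strategy).
#' @param params [nh_params()].
#' @param life_table [default_life_table()] or a custom table.
#' @param stool,col,policy test profiles and surveillance policy.
#' @param fit_screening_arm first-sensitivity-analysis flag.
#' @param ids explicit individual ids.
#' @return list: `person` (one row per individual; screened and unscreened
#'   diagnosis and death ages, resource counts, first-follow-up record,
#'   eligibility at age 40) and `amr` (per-exam-age adenomas present,
#'   missed, and exam counts, pooled over eligible individuals).
#' @examples
#' sim <- simulate_cohort(200, seed = 1, strat = strategy("FIT"),
#'                        arms = scenario_arms(build_scenarios(), 1))
#' head(sim$person)
#' @export
simulate_cohort <- function(n, seed = 1, strat = NULL, arms = NULL,
                            params = nh_params(),
                            life_table = default_life_table(),
                            stool = NULL, col = colonoscopy_profile(),
                            policy = surveillance_policy(),
                            fit_screening_arm = FALSE,
                            ids = seq_len(n)) {
  nh <- engine_nh_config(params, life_table)
  scr <- NULL
  if (!is.null(strat)) {
    if (is.null(arms)) stop("`arms` is required when screening")
    if (is.null(stool))
      stool <- test_profile(if (strat$modality == "mt-sDNA") "mt-sDNA"
                            else "FIT")
    scr <- engine_screen_config(strat, arms, stool, col, policy,
                                fit_screening_arm)
  }
  res <- cpp_simulate_cohort(as.double(seed), as.integer(ids), nh, scr)
  amr <- data.frame(age = res$amr_age, exams = res$amr_exams,
                    present = res$amr_present, missed = res$amr_missed)
  list(person = res$person, amr = amr[amr$exams > 0 | amr$present > 0, ])
}
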