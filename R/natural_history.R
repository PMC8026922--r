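# Latent disease engine: adenoma onset (non-homogeneous Poisson process under
# individual frailty), lesion growth (log-linear diameter), malignant
# transformation (size-dependent hazard integrated along the growth curve),
# preclinical sojourn, stage at diagnosis and CRC survival.
#
# Parameter values are NOT taken from any published calibration: they are
# package defaults chosen to give an epidemiologically plausible unscreened
# lifetime risk (see the methods vignette), and every one of them can be
# replaced through `nh_params()` to drop in an external calibrated set.

#' Natural-history parameters
#'
#' @param onset_breaks ages (years) starting the piecewise-constant segments
#'   of the baseline adenoma onset intensity.
#' @param onset_rates onset intensity (adenomas/year) per segment; the last
#'   segment runs to `max_age`. Multiplied by individual frailty.
#' @param max_age horizon for lesion generation.
#' @param frailty lognormal frailty parameters (`meanlog`, `sdlog`).
#' @param growth lognormal parameters of the time from onset (1 mm) to
#'   reaching 10 mm.
#' @param transition `rate_at_10mm` (per year) and `size_power`: the
#'   malignant-transformation hazard is `rate_at_10mm * (d/10)^size_power`
#'   below 10 mm and constant `rate_at_10mm` above.
#' @param sojourn lognormal parameters of the preclinical (screen-detectable)
#'   dwell time before symptomatic presentation.
#' @param stage_symptomatic,stage_screen stage I-IV probabilities at
#'   symptomatic versus screen detection (screen distribution must be
#'   shifted toward earlier stages).
#' @param survival_cure,survival_mean per-stage probability of no CRC death,
#'   and the exponential mean (years) of time to CRC death otherwise.
#' @param segment_probs location probabilities (rectum, distal colon,
#'   proximal colon, cecum).
#' @return list of class `nh_params`.
#' @export
nh_params <- function(onset_breaks = c(0, 20, 30, 40, 50, 60, 70, 80),
                      onset_rates = c(0, 0.002, 0.006, 0.012,
                                      0.018, 0.022, 0.024, 0.025),
                      max_age = 100,
                      frailty = list(meanlog = -0.5, sdlog = 1.0),
                      growth = list(meanlog = log(12), sdlog = 0.5),
                      transition = list(rate_at_10mm = 0.007, size_power = 3),
                      sojourn = list(meanlog = log(3), sdlog = 0.6),
                      stage_symptomatic = c(0.18, 0.32, 0.30, 0.20),
                      stage_screen = c(0.45, 0.30, 0.17, 0.08),
                      survival_cure = c(0.90, 0.70, 0.45, 0.05),
                      survival_mean = c(10, 7, 4, 1.5),
                      segment_probs = c(rectum = 0.25, distal = 0.35,
                                        proximal = 0.25, cecum = 0.15)) {
  p <- list(onset_breaks = onset_breaks, onset_rates = onset_rates,
            max_age = max_age, frailty = frailty, growth = growth,
            transition = transition, sojourn = sojourn,
            stage_symptomatic = stage_symptomatic,
            stage_screen = stage_screen,
            survival_cure = survival_cure, survival_mean = survival_mean,
            segment_probs = segment_probs)
  validate_nh_params(p)
}

validate_nh_params <- function(p) {
  stopifnot(length(p$onset_breaks) == length(p$onset_rates),
            !is.unsorted(p$onset_breaks, strictly = TRUE),
            all(p$onset_rates >= 0),
            p$transition$rate_at_10mm >= 0, p$transition$size_power > 0,
            abs(sum(p$stage_symptomatic) - 1) < 1e-8,
            abs(sum(p$stage_screen) - 1) < 1e-8,
            all(p$survival_cure >= 0 & p$survival_cure <= 1),
            all(p$survival_mean > 0),
            abs(sum(p$segment_probs) - 1) < 1e-8)
  # screen detection must not be later-staged than symptomatic detection
  if (any(cumsum(p$stage_screen) < cumsum(p$stage_symptomatic) - 1e-12))
    stop("stage_screen must be shifted toward earlier stages")
  class(p) <- "nh_params"
  p
}

# total baseline onset intensity integrated to max_age
onset_integral <- function(p) {
  hi <- c(p$onset_breaks[-1], p$max_age)
  sum(p$onset_rates * (hi - p$onset_breaks))
}

# invert the cumulative baseline intensity at `target` (R mirror of engine)
onset_invert_r <- function(p, target) {
  hi <- c(p$onset_breaks[-1], p$max_age)
  segs <- p$onset_rates * (hi - p$onset_breaks)
  acc <- 0
  for (i in seq_along(segs)) {
    if (target <= acc + segs[i] && p$onset_rates[i] > 0)
      return(p$onset_breaks[i] + (target - acc) / p$onset_rates[i])
    acc <- acc + segs[i]
  }
  p$max_age
}

# Poisson inverse CDF by forward summation (identical to the engine loop)
pois_inv_r <- function(u, lambda, cap = 64L) {
  if (lambda <= 0) return(0L)
  p <- exp(-lambda); cdf <- p; n <- 0L
  while (u > cdf && n < cap) { n <- n + 1L; p <- p * lambda / n; cdf <- cdf + p }
  n
}

#' Adenoma diameter along the growth curve
#'
#' Diameter is log-linear in time since onset: 1 mm at onset, exactly 10 mm
#' at `onset_age + time_to_10mm`, i.e. `d(a) = 10^((a - onset)/time_to_10mm)`.
#'
#' @param age exam age (>= `onset_age`).
#' @param onset_age adenoma onset age.
#' @param time_to_10mm years from onset to 10 mm.
#' @return diameter in mm.
#' @export
adenoma_diameter <- function(age, onset_age, time_to_10mm) {
  if (any(age < onset_age)) stop("age must be >= onset_age")
  10^((age - onset_age) / time_to_10mm)
}

#' Sample adenoma onset ages for one individual
#'
#' Non-homogeneous Poisson process with intensity `frailty *
#' baseline(age)`: the count is Poisson with the frailty-scaled integrated
#' intensity and onset ages are iid draws from the normalised baseline.
#'
#' @param ind one-row cohort entry (or list) with `id` and `frailty`.
#' @param params [nh_params()].
#' @param seed master seed.
#' @return numeric vector of onset ages (unordered; lesion k keeps draw
#'   index k as its substream key).
#' @export
sample_adenoma_onsets <- function(ind, params, seed) {
  lam0 <- onset_integral(params)
  n <- pois_inv_r(hash_u01(seed, ind$id, .P$n_adenomas, 0, 0),
                  ind$frailty * lam0)
  if (n == 0L) return(numeric())
  u <- hash_u01(seed, ind$id, .P$onset, seq_len(n), 0)
  vapply(u * lam0, function(t) onset_invert_r(params, t), 0)
}

# deterministic core of the transformation time (engine mirror):
# E is a unit-exponential variate, t10 the growth time to 10 mm
transition_time_from_E <- function(E, t10, params) {
  L <- log(10); A <- params$transition$rate_at_10mm
  pw <- params$transition$size_power
  if (A <= 0) return(Inf)
  H1 <- A * t10 / (pw * L) * (1 - 10^(-pw))
  t <- if (E <= H1) {
    t10 + t10 * log(10^(-pw) + E * pw * L / (A * t10)) / (pw * L)
  } else {
    t10 + (E - H1) / A
  }
  if (t > 150) Inf else t
}

#' Sample the malignant-transformation age of an adenoma
#'
#' The hazard increases with the current diameter (`rate_at_10mm *
#' (d/10)^size_power`, capped at its 10 mm value for larger lesions) and is
#' integrated in closed form along the log-linear growth curve.
#'
#' @param ind individual (list with `id`).
#' @param lesion lesion draw index (substream key).
#' @param onset_age,time_to_10mm lesion growth parameters.
#' @param params [nh_params()].
#' @param seed master seed.
#' @return transformation age, or `Inf` if the lesion never transforms.
#' @export
sample_transition <- function(ind, lesion, onset_age, time_to_10mm,
                              params, seed) {
  E <- -log(hash_u01(seed, ind$id, .P$transition, lesion, 0))
  onset_age + transition_time_from_E(E, time_to_10mm, params)
}

# stage from a single uniform against a CDF (engine mirror); 1..4
stage_from_u_r <- function(u, probs) {
  cdf <- cumsum(probs)
  s <- 1L
  while (s < 4L && u > cdf[s]) s <- s + 1L
  s
}

#' Sample preclinical sojourn and stage at symptomatic presentation
#'
#' @param ind individual (list with `id`).
#' @param lesion lesion draw index.
#' @param transition_age age at malignant transformation.
#' @param params [nh_params()].
#' @param seed master seed.
#' @return list with `sojourn`, `clinical_age` and `stage` (1-4, the stage
#'   if the cancer presents symptomatically).
#' @export
sample_sojourn_and_stage <- function(ind, lesion, transition_age,
                                     params, seed) {
  sj <- exp(params$sojourn$meanlog + params$sojourn$sdlog *
              qnorm(hash_u01(seed, ind$id, .P$sojourn, lesion, 0)))
  st <- stage_from_u_r(hash_u01(seed, ind$id, .P$stage, lesion, 0),
                       params$stage_symptomatic)
  list(sojourn = sj, clinical_age = transition_age + sj, stage = st)
}

#' Sample the CRC death age after diagnosis
#'
#' Mixture cure model: with the stage-specific cure probability there is no
#' CRC death; otherwise the residual time is exponential with the
#' stage-specific mean. Both draws use one uniform each per lesion, so under
#' paired draws survival is monotone in stage.
#'
#' @param ind individual (list with `id`).
#' @param lesion lesion draw index of the diagnosed cancer.
#' @param stage stage 1-4 at diagnosis.
#' @param dx_age age at diagnosis.
#' @param params [nh_params()].
#' @param seed master seed.
#' @return CRC death age (`Inf` if cured).
#' @export
crc_survival <- function(ind, lesion, stage, dx_age, params, seed) {
  stopifnot(stage %in% 1:4)
  u_cure <- hash_u01(seed, ind$id, .P$surv_cure, lesion, 0)
  if (u_cure < params$survival_cure[stage]) return(Inf)
  u_t <- hash_u01(seed, ind$id, .P$surv_time, lesion, 0)
  dx_age - params$survival_mean[stage] * log(u_t)
}

#' Generate the full latent disease history of one individual
#'
#' R reference implementation of the engine's per-person generator: onsets,
#' locations, growth times, transformation and clinical ages. Bit-identical
#' to the C++ fast path because both consume the same hashed substreams.
#'
#' @param ind one-row cohort entry with `id`, `frailty`,
#'   `other_cause_death_age`.
#' @param params [nh_params()].
#' @param seed master seed.
#' @return `disease_history` object (see [scripted_history()] for the
#'   scripted variant of the same class).
#' @export
sample_disease_history <- function(ind, params, seed) {
  onsets <- sample_adenoma_onsets(ind, params, seed)
  n <- length(onsets)
  seg_cum <- cumsum(params$segment_probs)
  les <- data.frame(onset_age = onsets,
                    time_to_10mm = numeric(n), transition_age = numeric(n),
                    clinical_age = numeric(n), segment = integer(n))
  for (k in seq_len(n)) {
    useg <- hash_u01(seed, ind$id, .P$segment, k, 0)
    sgm <- 1L
    while (sgm < 4L && useg > seg_cum[sgm]) sgm <- sgm + 1L
    les$segment[k] <- sgm
    les$time_to_10mm[k] <- exp(params$growth$meanlog + params$growth$sdlog *
                                 qnorm(hash_u01(seed, ind$id, .P$growth, k, 0)))
    les$transition_age[k] <- sample_transition(ind, k, onsets[k],
                                               les$time_to_10mm[k],
                                               params, seed)
    les$clinical_age[k] <- if (is.finite(les$transition_age[k])) {
      sample_sojourn_and_stage(ind, k, les$transition_age[k],
                               params, seed)$clinical_age
    } else Inf
  }
  les$lesion <- seq_len(n)
  structure(list(id = as.integer(ind$id), frailty = ind$frailty,
                 other_cause_death_age = ind$other_cause_death_age,
                 lesions = les, scripted = FALSE,
                 crc_death_age_override = NULL),
            class = "disease_history")
}

#' Natural course of a disease history (no screening)
#'
#' The first clinical presentation, if it occurs while the individual is
#' alive, becomes the CRC diagnosis; stage and survival are drawn from the
#' presenting lesion's substreams; death is the minimum of the CRC and
#' other-cause death ages.
#'
#' @param history a `disease_history`.
#' @param params [nh_params()].
#' @param seed master seed.
#' @return list: `dx_age` (NA if none), `stage`, `crc_death_age`,
#'   `death_age`, `life_years`, `eligible` (alive and CRC-free at exact age
#'   40, the per-1000 denominator condition).
#' @export
natural_course <- function(history, params = nh_params(), seed = 1) {
  les <- history$lesions
  ocd <- history$other_cause_death_age
  dx_age <- NA_real_; stage <- NA_integer_; crc_death <- Inf
  if (nrow(les) > 0 && any(is.finite(les$clinical_age))) {
    kk <- which.min(les$clinical_age)
    if (les$clinical_age[kk] < ocd) {
      dx_age <- les$clinical_age[kk]
      stage <- stage_from_u_r(hash_u01(seed, history$id, .P$stage,
                                       les$lesion[kk], 0),
                              params$stage_symptomatic)
      crc_death <- if (!is.null(history$crc_death_age_override)) {
        history$crc_death_age_override
      } else {
        crc_survival(history, les$lesion[kk], stage, dx_age, params, seed)
      }
    }
  }
  death <- min(ocd, crc_death)
  list(dx_age = dx_age, stage = stage,
       crc_death_age = if (is.finite(crc_death)) crc_death else NA_real_,
       death_age = death, life_years = death,
       eligible = ocd > 40 && !(!is.na(dx_age) && dx_age <= 40))
}
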