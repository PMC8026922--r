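# Synthetic birth cohort: other-cause mortality from a cohort life table,
# lognormal frailty on the adenoma onset intensity, and scripted disease
# histories for deterministic tests.

#' Read a cohort life table
#'
#' @param path CSV with columns `age` (integer years, starting at 0 and
#'   contiguous) and `qx` (annual probability of death from causes other
#'   than CRC). The terminal age must have `qx = 1`.
#' @return data.frame of class `life_table`.
#' @export
read_life_table <- function(path) {
  lt <- read.csv(path)
  validate_life_table(lt)
}

#' Packaged synthetic 1975-cohort life table
#'
#' A smooth all-cause-minus-CRC schedule (infant mortality bump, low rates
#' through midlife, Gompertz increase from age 30, terminal age 100) with
#' cohort life expectancy around 79 years. It is a synthetic stand-in with
#' the shape of a US 1975 birth-cohort table, not a published table; replace
#' it via [read_life_table()] for calibrated runs.
#'
#' @return data.frame of class `life_table`.
#' @export
default_life_table <- function() {
  path <- system.file("extdata", "life_table_1975_synthetic.csv",
                      package = "crcscreen", mustWork = TRUE)
  read_life_table(path)
}

validate_life_table <- function(lt) {
  if (!all(c("age", "qx") %in% names(lt)))
    stop("life table needs columns `age` and `qx`")
  lt <- lt[order(lt$age), c("age", "qx")]
  if (lt$age[1] != 0 || any(diff(lt$age) != 1))
    stop("life-table ages must be contiguous integers starting at 0")
  if (any(lt$qx < 0 | lt$qx > 1)) stop("qx must lie in [0, 1]")
  if (lt$qx[nrow(lt)] != 1) stop("terminal age must have qx = 1")
  class(lt) <- c("life_table", "data.frame")
  lt
}

# deterministic core: year from u1 by inverting the discrete survival curve,
# uniform timing within the year from u2 (must match the C++ engine)
ocd_from_u <- function(life_table, u1, u2) {
  Fk <- 1 - cumprod(1 - life_table$qx)   # P(death before age k), k = 1..K
  vapply(seq_along(u1), function(i) sum(Fk < u1[i]) + u2[i], 0)
}

#' Sample ages at death from other causes
#'
#' Inverts the discrete survival curve implied by the life table (so the
#' sampled year-of-death distribution matches it exactly) and places the
#' death uniformly within the year.
#'
#' @param life_table a [read_life_table()] table.
#' @param ids individual ids (their substreams are used).
#' @param seed master seed.
#' @return numeric ages in years.
#' @export
sample_other_cause_death <- function(life_table, ids, seed) {
  u1 <- hash_u01(seed, ids, .P$ocd, 0, 0)
  u2 <- hash_u01(seed, ids, .P$ocd, 1, 0)
  ocd_from_u(life_table, u1, u2)
}

#' Sample a synthetic birth cohort
#'
#' Each individual carries an id that names their random substreams, so the
#' same person sees identical draws under every screening strategy and
#' sensitivity scenario (common random numbers). Frailty is a lognormal
#' multiplier on the adenoma onset intensity.
#'
#' @param n cohort size.
#' @param life_table other-cause mortality table.
#' @param frailty list with `meanlog` and `sdlog` of the lognormal frailty.
#' @param seed master seed.
#' @param ids optional explicit ids (default `1:n`).
#' @param birth_year cohort birth year (metadata only).
#' @return data.frame of class `cohort`: `id`, `sex`, `birth_year`,
#'   `frailty`, `other_cause_death_age`.
#' @examples
#' head(sample_cohort(5, seed = 1))
#' @export
sample_cohort <- function(n, life_table = default_life_table(),
                          frailty = list(meanlog = -0.5, sdlog = 1.0),
                          seed = 1, ids = seq_len(n), birth_year = 1975L) {
  stopifnot(n >= 1, length(ids) == n)
  fr <- exp(frailty$meanlog +
            frailty$sdlog * qnorm(hash_u01(seed, ids, .P$frailty, 0, 0)))
  sex <- ifelse(hash_u01(seed, ids, .P$sex, 0, 0) < 0.5, "F", "M")
  out <- data.frame(id = as.integer(ids), sex = sex,
                    birth_year = birth_year, frailty = fr,
                    other_cause_death_age =
                      sample_other_cause_death(life_table, ids, seed))
  class(out) <- c("cohort", "data.frame")
  out
}

#' Construct a scripted disease history
#'
#' Bypasses all natural-history sampling: the lesion timeline and death age
#' are fixed by the caller, and downstream modules treat the result exactly
#' like a sampled history. Used for deterministic unit tests and worked
#' examples.
#'
#' @param lesions data.frame with columns `onset_age`, `time_to_10mm`, and
#'   optionally `transition_age` (default never), `clinical_age` (default
#'   `transition_age + sojourn` must then be given as `clinical_age`),
#'   `segment` (1 rectum, 2 distal, 3 proximal, 4 cecum; default 2). Use a
#'   zero-row data.frame (or `NULL`) for a lesion-free history.
#' @param other_cause_death_age fixed age at death from other causes.
#' @param id individual id (names the substreams for any remaining draws,
#'   e.g. test positivity).
#' @param frailty frailty value carried for completeness.
#' @param crc_death_age optional scripted CRC death age, overriding the
#'   survival draw after diagnosis.
#' @return object of class `disease_history`.
#' @examples
#' h <- scripted_history(data.frame(onset_age = 55, time_to_10mm = 7),
#'                       other_cause_death_age = 90)
#' adenoma_diameter(55 + 7, onset_age = 55, time_to_10mm = 7)
#' @export
scripted_history <- function(lesions = NULL, other_cause_death_age,
                             id = 0L, frailty = 1, crc_death_age = NULL) {
  if (is.null(lesions) || nrow(lesions) == 0) {
    lesions <- data.frame(onset_age = numeric(), time_to_10mm = numeric(),
                          transition_age = numeric(), clinical_age = numeric(),
                          segment = integer())
  } else {
    if (!all(c("onset_age", "time_to_10mm") %in% names(lesions)))
      stop("lesions need `onset_age` and `time_to_10mm`")
    if (is.null(lesions$transition_age)) lesions$transition_age <- Inf
    if (is.null(lesions$clinical_age)) {
      lesions$clinical_age <- ifelse(is.finite(lesions$transition_age),
                                     NA_real_, Inf)
      if (anyNA(lesions$clinical_age))
        stop("lesions with a transition_age need a clinical_age")
    }
    if (is.null(lesions$segment)) lesions$segment <- 2L
    bad <- is.finite(lesions$transition_age) &
      (lesions$transition_age <= lesions$onset_age |
         lesions$clinical_age <= lesions$transition_age)
    if (any(bad))
      stop("event ordering must satisfy onset < transition < clinical")
  }
  lesions$lesion <- seq_len(nrow(lesions))
  structure(list(id = as.integer(id), frailty = frailty,
                 other_cause_death_age = other_cause_death_age,
                 lesions = lesions, scripted = TRUE,
                 crc_death_age_override = crc_death_age),
            class = "disease_history")
}

#' @export
print.disease_history <- function(x, ...) {
  cat(sprintf("<disease_history> id %d, %d lesion(s), other-cause death %.1f%s\n",
              x$id, nrow(x$lesions), x$other_cause_death_age,
              if (isTRUE(x$scripted)) " (scripted)" else ""))
  invisible(x)
}
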