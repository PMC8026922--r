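# Aggregation of paired screened/unscreened person tables into per-1000
# outcome metrics, weighted adenoma miss rate (AMR) and adenoma detection
# rate (ADR).

#' Per-1000 normalisation
#'
#' All reported outcomes are per 1000 individuals alive and free of
#' diagnosed CRC at exact age 40 (the eligibility condition carried in the
#' person table).
#'
#' @param metric_sum summed metric over eligible individuals.
#' @param eligible_n number of eligible individuals.
#' @return `metric_sum / eligible_n * 1000`.
#' @export
per1000 <- function(metric_sum, eligible_n) {
  if (any(eligible_n <= 0)) stop("eligible_n must be positive")
  metric_sum / eligible_n * 1000
}

# helpers on the engine person table
crc_death_flag <- function(death_age, other_cause_death_age) {
  death_age < other_cause_death_age
}

#' Life-years gained by screening
#'
#' Undiscounted sum of (screened death age - unscreened death age) over
#' eligible individuals, per 1000. The two columns come from the same
#' engine pass so the comparison is paired within person (common random
#' numbers).
#'
#' @param person engine person table (must carry `eligible`, `death_age`,
#'   `death_age_unscreened`).
#' @return per-1000 life-years gained.
#' @export
lyg <- function(person) {
  if (!all(c("death_age", "death_age_unscreened") %in% names(person)))
    stop("person table must be paired (screened + unscreened death ages)")
  p <- person[person$eligible == 1, ]
  per1000(sum(p$death_age - p$death_age_unscreened), nrow(p))
}

#' Reduction in CRC incidence and mortality versus no screening
#'
#' @param person paired engine person table.
#' @return list with `incidence_reduction_pct` and
#'   `mortality_reduction_pct`, i.e. `100 * (1 - screened/unscreened)`;
#'   `NA` when the unscreened count is zero.
#' @export
reductions <- function(person) {
  p <- person[person$eligible == 1, ]
  cases_s <- sum(!is.na(p$dx_age))
  cases_u <- sum(!is.na(p$dx_age_unscreened))
  deaths_s <- sum(crc_death_flag(p$death_age, p$other_cause_death_age))
  deaths_u <- sum(crc_death_flag(p$death_age_unscreened,
                                 p$other_cause_death_age))
  list(incidence_reduction_pct =
         if (cases_u == 0) NA_real_ else 100 * (1 - cases_s / cases_u),
       mortality_reduction_pct =
         if (deaths_u == 0) NA_real_ else 100 * (1 - deaths_s / deaths_u))
}

#' Weighted mean adenoma miss rate
#'
#' The cross-sectional AMR at a single year of age is the number of missed
#' adenomas over the number of adenomas present among all colonoscopies
#' performed at that age (all indications pooled); the weighted mean uses
#' the colonoscopy count at each age as the weight. Ages with no adenomas
#' present carry no defined cross-section and are excluded.
#'
#' @param amr per-age table with columns `exams`, `present`, `missed` (as
#'   returned by [simulate_cohort()]).
#' @return weighted mean AMR in percent (`NA` if no exams saw adenomas).
#' @export
weighted_amr <- function(amr) {
  a <- amr[amr$present > 0 & amr$exams > 0, ]
  if (nrow(a) == 0) return(NA_real_)
  100 * sum(a$missed / a$present * a$exams) / sum(a$exams)
}

#' Adenoma detection rate at the first follow-up colonoscopy
#'
#' Among eligible individuals of a stool-test strategy, the fraction whose
#' first follow-up colonoscopy (after their first positive stool test)
#' detected at least one adenoma, and the mean age at those exams.
#'
#' @param person engine person table.
#' @return list with `adr_pct` and `mean_age` (`NA` if no follow-up
#'   colonoscopies occurred).
#' @export
adr_first_followup <- function(person) {
  p <- person[person$eligible == 1 & !is.na(person$first_followup_detected), ]
  if (nrow(p) == 0) return(list(adr_pct = NA_real_, mean_age = NA_real_))
  list(adr_pct = 100 * mean(p$first_followup_detected),
       mean_age = mean(p$first_followup_age))
}

#' Life-years gained relative to the colonoscopy strategy
#'
#' Strategies within 90% of the colonoscopy strategy's LYG are considered
#' of comparable effectiveness.
#'
#' @param lyg_strategy,lyg_colonoscopy per-1000 LYG values computed under
#'   the same scenario.
#' @return percent, `100 * lyg_strategy / lyg_colonoscopy`.
#' @export
pct_lyg_vs_colonoscopy <- function(lyg_strategy, lyg_colonoscopy) {
  if (any(lyg_colonoscopy == 0)) return(NA_real_)
  100 * lyg_strategy / lyg_colonoscopy
}

#' Assemble the outcome row for one strategy x scenario cell
#'
#' @param sim result of [simulate_cohort()] run with a strategy.
#' @param strategy_label,scenario labels recorded in the row.
#' @return one-row data.frame with the per-1000 outcomes, reductions,
#'   weighted AMR and first-follow-up ADR.
#' @export
outcome_table <- function(sim, strategy_label = NA_character_,
                          scenario = NA_integer_) {
  p <- sim$person[sim$person$eligible == 1, ]
  ne <- nrow(p)
  dx <- !is.na(p$dx_age)
  red <- reductions(sim$person)
  adr <- adr_first_followup(sim$person)
  data.frame(
    strategy = strategy_label, scenario = scenario, n_eligible = ne,
    lyg = lyg(sim$person),
    crc_cases = per1000(sum(dx), ne),
    crc_deaths = per1000(sum(crc_death_flag(p$death_age,
                                            p$other_cause_death_age)), ne),
    crc_cases_unscreened = per1000(sum(!is.na(p$dx_age_unscreened)), ne),
    crc_deaths_unscreened =
      per1000(sum(crc_death_flag(p$death_age_unscreened,
                                 p$other_cause_death_age)), ne),
    incidence_reduction_pct = red$incidence_reduction_pct,
    mortality_reduction_pct = red$mortality_reduction_pct,
    stool_tests = per1000(sum(p$n_stool_tests), ne),
    colonoscopies = per1000(sum(p$n_colonoscopies), ne),
    complications = per1000(sum(p$n_complications), ne),
    life_years_with_crc = per1000(sum(ifelse(dx, p$death_age - p$dx_age, 0)),
                                  ne),
    weighted_amr_pct = weighted_amr(sim$amr),
    adr_first_followup_pct = adr$adr_pct,
    mean_age_first_followup = adr$mean_age)
}
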