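# Scenario construction: indication-specific colonoscopy adenoma sensitivity.
#
# The base-case adenoma sensitivities (75% small, 85% medium, 95% large) are
# split symmetrically on the log-odds scale into a screening arm and a
# follow-up/surveillance arm, so that the two arms differ by a prescribed
# log odds ratio while their logit midpoint stays at the base value.

#' Adenoma size classes
#'
#' Diameter bounds used throughout the model: small 1-5 mm, medium 6-9 mm,
#' large >= 10 mm (classification of a continuous diameter d uses
#' d < 6, 6 <= d < 10, d >= 10).
#'
#' @return data.frame with columns `size_class`, `lower_mm`, `upper_mm`.
#' @export
size_classes <- function() {
  data.frame(size_class = c("small", "medium", "large"),
             lower_mm = c(1, 6, 10),
             upper_mm = c(5, 9, Inf))
}

#' Classify a diameter in mm into a size class
#' @param d_mm numeric diameter(s) in mm (>= 1).
#' @return character vector in `c("small","medium","large")`.
#' @export
size_class_of <- function(d_mm) {
  ifelse(d_mm < 6, "small", ifelse(d_mm < 10, "medium", "large"))
}

#' Split a base sensitivity into screening and follow-up arms
#'
#' Symmetric log-odds split: the screening arm is `plogis(qlogis(base) -
#' lnOR/2)` and the follow-up/surveillance arm `plogis(qlogis(base) +
#' lnOR/2)`, so the two arms differ by exactly `lnOR` on the log-odds scale
#' and their logit midpoint equals the base value.
#'
#' @param base base-case sensitivity, strictly in (0, 1). Vectorised.
#' @param lnOR log odds ratio of follow-up versus screening colonoscopy.
#' @return list with numeric components `screening` and `followup`.
#' @examples
#' adjusted_pair(0.75, 1.20)   # scenario with lnOR 1.2 about the 75% base
#' @export
adjusted_pair <- function(base, lnOR) {
  if (any(!is.finite(base)) || any(base <= 0) || any(base >= 1))
    stop("`base` must be strictly inside (0, 1)")
  if (any(!is.finite(lnOR)))
    stop("`lnOR` must be finite")
  lb <- qlogis(base)
  list(screening = plogis(lb - lnOR / 2),
       followup  = plogis(lb + lnOR / 2))
}

#' Build the sensitivity scenario grid
#'
#' Ten scenarios: scenario 1 ("no impact") has both arms at the base values;
#' scenarios 2-10 are the 3 x 3 grid of anchor log odds ratios at the large
#' size class (0, 1, 2; "small"/"medium"/"large impact" groups) and constant
#' slopes (0.15, 0.30, 0.60) added per size step down, so
#' `lnOR(large) = anchor`, `lnOR(medium) = anchor + slope`,
#' `lnOR(small) = anchor + 2 * slope`.
#'
#' @param base named numeric of base sensitivities for `small`, `medium`,
#'   `large` adenomas.
#' @param anchors anchor log odds ratios at the large size class.
#' @param slopes per-size-step log odds ratio increments.
#' @return data.frame of class `scenario_table` with one row per scenario x
#'   size class: `scenario`, `group`, `size_class`, `lnOR`, `slope`,
#'   `screening`, `followup`, and the percent columns `screening_pct`,
#'   `followup_pct` rounded half-up to one decimal.
#' @examples
#' tab <- build_scenarios()
#' subset(tab, scenario == 7 & size_class == "small")
#' @export
build_scenarios <- function(base = c(small = 0.75, medium = 0.85, large = 0.95),
                            anchors = c(0, 1, 2),
                            slopes = c(0.15, 0.30, 0.60)) {
  stopifnot(all(c("small", "medium", "large") %in% names(base)))
  cls <- c("small", "medium", "large")
  rows <- list()
  add <- function(scenario, group, lnOR, slope) {
    pr <- adjusted_pair(base[cls], rev(lnOR))   # lnOR given large->small
    data.frame(scenario = scenario, group = group, size_class = cls,
               lnOR = rev(lnOR), slope = slope,
               screening = unname(pr$screening),
               followup = unname(pr$followup))
  }
  rows[[1]] <- add(1L, "no impact", c(0, 0, 0), NA_real_)
  groups <- c("small impact", "medium impact", "large impact")
  id <- 1L
  for (gi in seq_along(anchors)) {
    for (sl in slopes) {
      id <- id + 1L
      lnOR <- anchors[gi] + (0:2) * sl       # large, medium, small
      rows[[id]] <- add(id, groups[gi], lnOR, sl)
    }
  }
  out <- do.call(rbind, rows)
  out$screening_pct <- round_half_up(100 * out$screening, 1)
  out$followup_pct <- round_half_up(100 * out$followup, 1)
  rownames(out) <- NULL
  class(out) <- c("scenario_table", "data.frame")
  out
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), the convention used
#' when printing sensitivity percentages, as opposed to R's banker rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Extract the sensitivity arms of one scenario
#'
#' @param tab a `scenario_table` from [build_scenarios()].
#' @param scenario scenario id (1-10).
#' @return list with numeric `screening` and `followup`, each length 3
#'   (small, medium, large), plus the scenario id and group label.
#' @export
scenario_arms <- function(tab, scenario) {
  rows <- tab[tab$scenario == scenario, ]
  if (nrow(rows) != 3L) stop("scenario ", scenario, " not found")
  ord <- match(c("small", "medium", "large"), rows$size_class)
  list(scenario = scenario, group = rows$group[1],
       screening = setNames(rows$screening[ord], c("small", "medium", "large")),
       followup = setNames(rows$followup[ord], c("small", "medium", "large")))
}

#' Write a scenario table to CSV
#'
#' Columns mirror the published layout: scenario, group, size_class, lnOR,
#' slope, screening_pct, followup_pct.
#'
#' @param tab a `scenario_table`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_scenario_table <- function(tab, path) {
  cols <- c("scenario", "group", "size_class", "lnOR", "slope",
            "screening_pct", "followup_pct")
  write.csv(tab[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @export
print.scenario_table <- function(x, ...) {
  cat("Colonoscopy sensitivity scenarios (screening vs follow-up/surveillance)\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
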