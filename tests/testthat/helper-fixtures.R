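# Shared fixtures. The published sensitivity table (percent, one decimal)
# is transcribed once here; scenario rows are (screening, followup) by
# size class small/medium/large.
published_table1 <- local({
  rows <- list(
    list(1,  "no impact",     c(NA,   NA,   NA),  c(75.0, 75.0), c(85.0, 85.0), c(95.0, 95.0)),
    list(2,  "small impact",  c(0.30, 0.15, 0.00), c(72.1, 77.7), c(84.0, 85.9), c(95.0, 95.0)),
    list(3,  "small impact",  c(0.60, 0.30, 0.00), c(69.0, 80.2), c(83.0, 86.8), c(95.0, 95.0)),
    list(4,  "small impact",  c(1.20, 0.60, 0.00), c(62.2, 84.5), c(80.8, 88.4), c(95.0, 95.0)),
    list(5,  "medium impact", c(1.30, 1.15, 1.00), c(61.0, 85.2), c(76.1, 91.0), c(92.0, 96.9)),
    list(6,  "medium impact", c(1.60, 1.30, 1.00), c(57.4, 87.0), c(74.7, 91.6), c(92.0, 96.9)),
    list(7,  "medium impact", c(2.20, 1.60, 1.00), c(50.0, 90.0), c(71.8, 92.7), c(92.0, 96.9)),
    list(8,  "large impact",  c(2.30, 2.15, 2.00), c(48.7, 90.5), c(65.9, 94.3), c(87.5, 98.1)),
    list(9,  "large impact",  c(2.60, 2.30, 2.00), c(45.0, 91.7), c(64.2, 94.7), c(87.5, 98.1)),
    list(10, "large impact",  c(3.20, 2.60, 2.00), c(37.7, 93.7), c(60.7, 95.4), c(87.5, 98.1)))
  do.call(rbind, lapply(rows, function(r) {
    data.frame(scenario = r[[1]], group = r[[2]],
               size_class = c("small", "medium", "large"),
               lnOR = r[[3]],
               screening_pct = c(r[[4]][1], r[[5]][1], r[[6]][1]),
               followup_pct = c(r[[4]][2], r[[5]][2], r[[6]][2]))
  }))
})

# a stool profile that never triggers a colonoscopy (all-negative tests)
silent_stool <- function(name = "FIT") {
  test_profile(name, sens_crc = 0, sens_advanced_adenoma = 0,
               sens_nonadvanced_adenoma = 0, specificity = 1)
}

# natural-history parameters with no adenomas at all
no_lesion_params <- function() {
  nh_params(onset_rates = rep(0, 8))
}

# constant-intensity onset over one age window, deterministic frailty = 1
flat_onset_params <- function(rate = 0.02, to = 50, ...) {
  nh_params(onset_breaks = c(0, to), onset_rates = c(rate, 0),
            frailty = list(meanlog = 0, sdlog = 0), ...)
}

# a life table that is certain death in year `at`
point_life_table <- function(at = 80) {
  q <- rep(0, 101)
  q[(at:100) + 1] <- 1
  validate_crcscreen_lt(data.frame(age = 0:100, qx = q))
}

validate_crcscreen_lt <- function(df) {
  tmp <- tempfile(fileext = ".csv")
  write.csv(df, tmp, row.names = FALSE)
  on.exit(unlink(tmp))
  read_life_table(tmp)
}
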