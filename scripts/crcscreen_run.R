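#!/usr/bin/env Rscript
# Thin command-line entry over the package:
#   Rscript scripts/crcscreen_run.R scenarios -o table1.csv
#   Rscript scripts/crcscreen_run.R run --n 200000 --seed 7 --out results/ \
#       [--analysis primary|sa1] [--scenarios 1,10]

suppressPackageStartupMessages(library(crcscreen))

args <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(args)) args[1] else "help"
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

if (cmd == "scenarios") {
  out <- get_arg("-o", "table1.csv")
  base <- as.numeric(strsplit(get_arg("--base", "0.75,0.85,0.95"), ",")[[1]])
  anchors <- as.numeric(strsplit(get_arg("--anchors", "0,1,2"), ",")[[1]])
  slopes <- as.numeric(strsplit(get_arg("--slopes", "0.15,0.3,0.6"), ",")[[1]])
  tab <- build_scenarios(setNames(base, c("small", "medium", "large")),
                         anchors, slopes)
  write_scenario_table(tab, out)
  message("wrote ", out)
} else if (cmd == "run") {
  scen <- as.integer(strsplit(get_arg("--scenarios", "1,2,3,4,5,6,7,8,9,10"),
                              ",")[[1]])
  cfg <- experiment_config(
    n = as.numeric(get_arg("--n", "200000")),
    seed = as.integer(get_arg("--seed", "1")),
    scenarios = scen,
    analysis = if (get_arg("--analysis", "primary") == "sa1")
      "fit_screening_arm" else "primary",
    out_dir = get_arg("--out", "results"))
  out <- run_grid(cfg)
  print(out)
} else {
  cat("usage: crcscreen_run.R scenarios|run [options]\n")
}
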