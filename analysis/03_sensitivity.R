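#!/usr/bin/env Rscript
# Step 3 — sensitivity scenarios.
#
# Re-runs the pipeline under the four named scenarios (penalty ignored,
# reduced durations, two alternative incidence-ratio sets) and reports
# percentage changes against the core model at world, income-group and region
# level. Outputs under results/sensitivity/.

library(t1dglobal)

dir.create("results/sensitivity", showWarnings = FALSE, recursive = TRUE)
tbl <- read_country_table("results/inputs/countries.csv")
schedule <- read_survival_schedule("results/inputs/schedule.yaml")
core <- estimate_burden(tbl, schedule)

scen_files <- list.files(
  system.file("extdata", "scenarios", package = "t1dglobal"),
  full.names = TRUE)

for (f in scen_files) {
  spec <- read_scenario(f)
  scen <- run_scenario(tbl, schedule, spec)
  cmp <- dplyr::bind_rows(
    compare_to_core(core, scen, "world"),
    compare_to_core(core, scen, "income_group"),
    compare_to_core(core, scen, "region")
  )
  slug <- gsub("\\W+", "_", spec$name)
  readr::write_csv(cmp, sprintf("results/sensitivity/%s.csv", slug))
  w <- cmp[cmp$group == "World", ]
  cat(sprintf("%-28s incident %+6.1f%%   prevalent %+6.1f%%\n",
              spec$name, w$incident_change_pct, w$prevalent_change_pct))
}
cat("\nPer-group comparisons written to results/sensitivity/.\n")
cat("Duration-only scenarios leave incident counts unchanged by construction;\n")
cat("the incidence-ratio scenarios move incident and prevalent cases together.\n")
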