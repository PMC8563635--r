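#!/usr/bin/env Rscript
# Step 2 — core burden estimates.
#
# Runs the estimation chain on the inputs from step 1: scale childhood
# incidence to adult bands (1 / 0.50 / 0.30 / 0.25), apply to populations,
# penalise durations by child mortality, form steady-state prevalence and
# reallocate it to attained ages. Writes per-country estimates, the headline
# summary table and share tables under results/core/.

library(t1dglobal)

dir.create("results/core", showWarnings = FALSE, recursive = TRUE)
tbl <- read_country_table("results/inputs/countries.csv")
schedule <- read_survival_schedule("results/inputs/schedule.yaml")

est <- estimate_burden(tbl, schedule)
readr::write_csv(est, "results/core/estimates.csv")
emit_table1(est, "results/core/table1.csv")

for (spec in list(c("onset_age", "incident"), c("attained_age", "prevalent"),
                  c("income", "incident"), c("income", "prevalent"),
                  c("region", "incident"), c("region", "prevalent"))) {
  st <- share_table(est, spec[1], spec[2])
  readr::write_csv(st, sprintf("results/core/shares_%s_%s.csv",
                               spec[2], spec[1]))
}

world <- aggregate_estimates(est, "world")
cat(sprintf("World incident cases:  %s /yr\n",
            format(round(world$inc_total), big.mark = ",")))
cat(sprintf("World prevalent cases: %s\n",
            format(round(world$prev_total), big.mark = ",")))
cat(sprintf("Crude prevalence: %.2f per 1000; standardised: %.2f per 1000\n",
            world$crude_per1000, world$std_per1000))
att <- share_table(est, "attained_age", "prevalent")
cat("Prevalent cases by attained age (0-14 / 15-39 / 40-64 / 65+):",
    paste0(att$share_pct_rounded, "%", collapse = " / "), "\n")
inc <- share_table(est, "income", "incident")
cat("Incident share of high-income countries:",
    sprintf("%.0f%%\n", inc$share_pct[inc$group == "HIC"]))
cat("Headline table written to results/core/table1.csv\n")
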