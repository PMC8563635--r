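# t1dglobal

Country, regional and global estimates of incident and prevalent cases of
type 1 diabetes across all ages, from the three inputs that are actually
available at global scale: childhood (0–14 years) incidence registries,
under-5 child mortality rates, and population counts by age band.

Direct measurements of adult type 1 diabetes incidence and of survival with
the disease exist for only a handful of high-income countries, so global
burden numbers have to be modelled. This package implements, as a tested and
reusable pipeline, the estimation chain used for the 2017 global estimates:

1. **Adult incidence by scaling.** For each country, age-band incidence
   rates are the childhood rate times fixed ratios
   `IR(0–14) : IR(15–39) : IR(40–64) : IR(65+) = 1.00 : 0.50 : 0.30 : 0.25`
   (Danish registry-derived; an alternative set 1 : 0.57 : 0.28 : 0.19 from a
   large Chinese study ships as a preset). Incident cases are
   `rate × population / 100 000` per band.
2. **Duration with a child-mortality penalty.** Mean years lived with the
   disease from onset are a band-specific global maximum
   (60.4 / 43.4 / 21.1 / 8.5 years, Danish remaining-lifetime estimates)
   scaled down by `Pen = CM / 130`, where CM is the country's under-5
   mortality per 1000 live births and 130 sits just above the highest 2017
   national value: `D = max(D_max × (1 − Pen), 0.5)`.
3. **Steady-state prevalence.** Assuming annual new cases balance annual
   deaths among cases, `prevalence = incidence × mean duration` per onset
   band; prevalent cases are then reallocated to *attained*-age bands by the
   person-years an incident case is expected to live in each band, computed
   from a cumulative-survival schedule.
4. **Reporting.** Aggregation by World Bank income group, UN region and
   world; crude and WHO-world-standard age-standardised prevalence per 1000;
   headline and share tables.
5. **Sensitivity scenarios.** Penalty ignored, reduced durations, and two
   alternative incidence-ratio sets, each a re-run of the identical pipeline
   with one override.

Because the real per-country input tables are not redistributable, the
package includes a seeded synthetic world generator with the same structure
(~200 countries, incidence spanning two orders of magnitude, child mortality
tied to income group, donor countries for the ~half of countries without a
registry study), and an independent cohort-simulation oracle that checks the
steady-state arithmetic by brute-force bookkeeping.

## Worked example

The `analysis/` scripts run the full study on a seeded synthetic world:

```sh
Rscript analysis/01_generate_inputs.R   # build inputs under results/inputs/
Rscript analysis/02_core_estimates.R    # core model -> results/core/
Rscript analysis/03_sensitivity.R       # scenarios  -> results/sensitivity/
Rscript analysis/04_model_checks.R      # validation -> results/checks/
```

Output of step 2 (seed 2017):

```
World incident cases:  239,247 /yr
World prevalent cases: 8,559,463
Crude prevalence: 1.14 per 1000; standardised: 1.06 per 1000
Prevalent cases by attained age (0-14 / 15-39 / 40-64 / 65+): 7% / 32% / 38% / 23%
Incident share of high-income countries: 33%
```

Roughly 240 thousand people develop type 1 diabetes per year in this
synthetic world and 8.6 million live with it — about 1.1 per 1000 people.
Only 7% of prevalent cases are children even though all input incidence data
are from childhood registries: most people living with the disease acquired
it years ago and are now adults. Step 3 prints the scenario deltas
(e.g. removing the child-mortality penalty raises world prevalence by about
25% while leaving incidence untouched; scaling all adult bands at 0.5 raises
incidence by ~17%), and step 4 confirms the analytic model against the
cohort simulation (totals agree to <0.1%) and the structural invariants.

Equivalent programmatic use:

```r
library(t1dglobal)
gen <- generate_country_table(synthetic_config(seed = 2017))
tbl <- assign_missing_incidence(gen$table, gen$donor_map)
sch <- generate_survival_schedule(2017)
est <- estimate_burden(tbl, sch)
summarise_table1(est)   # 11 x 13 headline table
```

`run_pipeline(run_config(...))` wraps the whole chain, including scenario
files and a reproducibility manifest.

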