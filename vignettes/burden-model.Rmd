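---
title: "Estimating the global burden of type 1 diabetes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the global burden of type 1 diabetes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1dglobal)
```

## The estimation problem

Type 1 diabetes incidence has been measured in standardised childhood
(0–14 years) registries in about half the world's countries, but adult
incidence and survival with the disease are documented in very few places,
almost all of them high-income. Estimating how many people *live* with the
disease worldwide therefore requires a model that extrapolates from what is
measured (childhood incidence, demography, child mortality) to what is not
(adult incidence, disease duration, the age distribution of survivors).
This vignette describes the model this package implements, the choices made
where the design was open, and what the accompanying tests do and do not
establish.

All computation happens at the resolution of four age bands — 0–14, 15–39,
40–64 and 65+ years — a compromise between age detail and the actual
resolution of the available epidemiology. Bands are half-open integer-year
intervals; the open 65+ band is closed at `cap_age` (default 99 years) for
person-year arithmetic.

## Core model

**Incidence.** For country $c$ with childhood incidence $IR_c$ (cases per
100 000 person-years), the rate in band $b$ is $IR_c \cdot r_b$ with fixed
ratios $r = (1.00, 0.50, 0.30, 0.25)$, derived from Danish registry data and
applied globally. Incident cases are $IR_c \, r_b \, N_{cb} / 10^5$ for band
population $N_{cb}$. An alternative ratio set $(1, 0.57, 0.28, 0.19)$
observed in a Chinese population study ships as the `"china"` preset. Counts
stay real-valued through the pipeline; rounding happens only in reporting
(half away from zero, two decimals on the thousands scale — the convention
of the spreadsheet lineage of this kind of estimation).

**Duration.** Mean years lived with the disease from onset in band $b$ is

$$D_{cb} = \max\bigl(D^{\max}_b (1 - \mathrm{Pen}_c),\ 0.5\bigr), \qquad
\mathrm{Pen}_c = \mathrm{CM}_c / 130,$$

where $D^{\max} = (60.4, 43.4, 21.1, 8.5)$ years are remaining-lifetime
estimates for Danish patients (close to Scottish figures), $\mathrm{CM}_c$
is the country's under-5 mortality per 1000 live births, and 130 sits just
above the highest national value in 2017, so $\mathrm{Pen} \in [0, 1)$ on
real inputs. Child mortality is used as the health-system proxy because it
is largely unaffected by HIV/AIDS mortality, unlike full life expectancy.
Two boundary decisions were open and are resolved as follows:

* the 0.5-year global minimum is implemented as a hard floor on the
  formula's output, which reproduces the stated behaviour at both extremes
  (full duration at $\mathrm{Pen}=0$, half a year where insulin access is
  essentially absent);
* $\mathrm{CM} > 130$ (impossible for the 2017 era, possible for synthetic
  stress inputs) clamps the penalty to 1 with a warning rather than
  erroring, so the model degrades gracefully.

**Prevalence.** Under epidemiological steady state (annual new cases equal
annual deaths among cases), prevalence is incidence times mean duration,
applied per onset band: $P_{cb} = I_{cb} D_{cb}$. The steady-state
assumption is the model's central approximation; it is violated wherever
incidence trends upward or survival is improving, which biases prevalence
estimates in a direction that depends on the country. The package therefore
ships an independent check (below) of the *arithmetic*, while the
*assumption* itself remains a documented limitation.

**Attained age.** A prevalent person belongs to one onset band forever but
moves through attained-age bands as they survive. Reallocation uses a
cumulative-survival schedule: for each onset band, the mean onset age
$a_g$ (defaults 7.5, 27, 52, 72 years) and the survival probability from
onset to the end of each later band. Expected person-years per incident case
in each attained band come from trapezoidal integration of the
piecewise-linear survival curve: from $a_g$ (survival 1) to the onset band's
end, between band-end knots thereafter, and linearly to zero at `cap_age`
inside the open 65+ band. Linear interpolation between knots is the minimal
assumption given that schedules provide survival only at band ends.
Normalised person-years give allocation weights $w_{gb}$ and
$P^{att}_{cb} = \sum_g P_{cg} w_{gb}$.

Because the penalty already scales totals through $D$, the default
allocation uses penalty-free weights and rescales person-years
proportionally: band shares are penalty-invariant, mass is conserved
exactly, and the attained-age totals match $I \times D$ by construction. A
plausible alternative reading — that worse survival curtails old age
specifically — is available as `tail_truncate = TRUE`, which removes
person-years from the oldest attained bands first. The default was chosen
because it is deterministic, conserves mass trivially, and never produces
shares more extreme than the schedule itself.

**Reporting.** Aggregates are plain sums over member countries (World Bank
income groups, UN regions, world). Crude prevalence is per-1000 over the
group population. Age-standardised prevalence weights the band-specific
rates by the WHO world standard population 2000–2025, aggregated once from
its published eighteen 5-year proportions into the four bands
(`who_standard_weights(five_year = TRUE)` exposes the source table; the
published column sums to 100.03 because of rounding in the source, so the
four-band weights are normalised). Printed tables round totals computed
from unrounded sums, so a printed total may differ from the sum of its
printed cells by up to 0.01 thousand; this reconciliation rule is
documented rather than "fixed" because it mirrors how such tables are
produced in practice.

## The cohort-simulation oracle

`simulate_steady_state()` is a deliberately independent implementation of
the same question: inject each year's incident cases at their band's mean
onset age, age everyone in 1-year steps, kill according to the schedule's
survival curve time-rescaled so that remaining life expectancy from onset
equals the supplied durations, and read off the surviving population once
the system is stationary. It shares no code path with the analytic
product-and-allocate pipeline (midpoint sampling of the survival curve
versus trapezoid integration). Totals agree with the analytic model to well
under 1% across seeds; attained-band *values* can differ by a few percent
in narrow bands because mid-year counting smears band boundaries by half a
year, which is why the equivalence check compares totals at a 2% tolerance.

## Synthetic inputs

The real country-level inputs are registry compilations and UN tables that
are not redistributable, so the package generates synthetic worlds with
their statistical structure. Defaults (see `synthetic_config()`):

* **~200 countries**, income mix 30/28/27/15% (HIC/UMIC/LMIC/LIC) and a
  region mix approximating the UN country lists (North America has few
  countries, so its default share is 3%).
* **Childhood incidence** log-normal with log-mean $\log 2.5$ and log-sd
  1.15: median ≈ 2.5 per 100 000/yr and a 99% range of roughly 0.1–60,
  matching the two-orders-of-magnitude spread between East Asian and Nordic
  registries. The distribution is the simplest one reproducing that
  right skew.
* **Child mortality** uniform within income-group intervals (HIC 2–10,
  UMIC 5–25, LMIC 15–70, LIC 40–125 per 1000), all below the penalty
  ceiling of 130, because the penalty mechanism is only meaningful if CM
  covaries with income.
* **Populations** log-normal national totals rescaled to 7.5 billion, with
  the childhood population share interpolating from ~18% in the
  lowest-mortality countries to ~42% near the ceiling (the demographic
  transition), plus gamma noise.
* **Half the countries lack an observed study**; each is paired with a
  same-region observed donor. One randomly chosen country per region is
  always kept observed so a donor exists for every feasible configuration —
  mirroring the real inputs, where every region contains at least one
  registry study. Donor choice in the real analysis is expert judgement,
  so here (as there) the map is *input*, not computed: rates are copied
  directly.

A synthetic survival schedule is generated per seed: a Weibull curve per
onset band (shape drawn from [1.5, 3]), evaluated at the band-end knots,
with the scale calibrated by root finding so that the *implied* expectancy —
the person-year total under the same trapezoid-plus-linear-tail integration
the allocation uses — equals that band's $D^{\max}$. The 65+ onset band has
no interior knots, so under the linear-tail rule its implied expectancy is
$(\text{cap} - a_4)/2$ and the mean onset age is the calibrated quantity:
$a_4 = \text{cap} - 2 \times 8.5 = 82$ years by default. Targets above what
the knot representation can express (e.g. 90 years from onset at 7.5 with a
linear tail) raise a calibration error rather than being silently clipped.

What the generator does **not** emulate: spatial correlation between
neighbouring countries, the long upper tail of national populations (China
and India are larger than any log-normal draw at this scale), reporting-year
heterogeneity, and any real covariance between incidence and income. Tests
passing on synthetic worlds therefore establish the *pipeline's* arithmetic
and invariances, not the accuracy of the published country estimates.

## Sensitivity scenarios

Scenarios are single-override re-runs: `override_penalty = 0` (everyone
attains maximum duration — the ceiling on prevalence at current incidence),
`duration_scale` (a common multiplier on $D^{\max}$; prevalence scales by
exactly that factor, a useful linearity check), and replacement ratio sets.
The shipped YAML files for "reduced mean duration" (scale 0.72) and
"changed incidence scaling 1" (ratios 1/0.40/0.20/0.15) carry synthetic
placeholder values, clearly labelled in the files, because the original
scenario parameters are not published in the main text; the uniform-0.5
ratio set of "changed incidence scaling 2" is as published. Duration-only
scenarios leave incident counts bit-identical by construction, and the
tests assert exactly that.

## Numerical and interface choices

* Band populations, rates and counts are plain doubles; no rounding until
  reporting. Conservation of the allocation step holds to machine precision
  (~1e-16 relative, asserted at 1e-9 over 1000 random inputs).
* CSV is the interchange format (UTF-8, `.` decimal, fixed column names,
  empty string for missing values — the region code "NA" for North America
  is a real value). `read_country_table()` validates on read; strict mode
  rejects, lenient mode drops rows with logged reasons.
* Chained donor extrapolation (donor itself extrapolated) is refused: no
  published rule exists for it.
* Survival schedules serialise as YAML: per onset band, the mean onset age
  and `(band_end_age, cum_survival)` pairs.
* Problem sizes in the test suite and acceptance script — 200-country
  worlds, 5-seed oracle comparisons, 1000-draw conservation checks, 1-year
  simulation steps over a ~200-year horizon — were chosen so the full suite
  runs in well under a minute while exercising every code path at the
  study's natural scale.

## Known limitations

The steady-state assumption, band-constant incidence ratios applied
globally, a single scalar penalty per country, one world survival schedule,
and no sex or urban/rural stratification are all inherited from the model
being implemented; they are the price of estimating from data that exist.
Within-band age gradients are not modelled. The mean onset ages affect only
within-band person-year overlaps, not totals. Published percentage outcomes
of the two placeholder scenarios are not reproducible without the original
country inputs and are treated as documentation, not test targets.
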