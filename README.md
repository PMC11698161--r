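# polypharm

Tools for measuring **out-of-hospital CNS-active polypharmacy** — the
concurrent use of three or more centrally acting medications — in cohorts of
adults aged 60+ from pharmacy claims. The package is aimed at
pharmacoepidemiologists who have a patient baseline table and a dated
prescription-fill table (ATC-coded, no days-of-supply field) and need
defensible prevalence and association estimates from them.

## What it computes

Six medication classes count as CNS-active: antidepressants (SSRI/SNRI/TCA
under the strict default), anti-epileptics, antipsychotics, benzodiazepines,
Z-drugs and opioids, resolved from ATC codes by a longest-prefix-wins rule
table with user overrides.

A fill of agent *a* in month *m* implies exposure over months
[*m*, *m* + *g*]; the grace period *g* absorbs refill gaps and stockpiling.
Three exposure rules are built in: `month_grace(1)` (main), `month_grace(2)`
and `same_week` (ISO week, no grace) as sensitivity analyses. A
**polypharmacy event** is a patient-period with ≥ 3 distinct concurrent
agents (distinct by 7-character ATC code — three different benzodiazepines
qualify), with no restriction on class composition and multiple events per
patient.

From the events the package computes:

* **period prevalence** `x/n` with Clopper–Pearson exact intervals
  (Beta-quantile endpoints `qbeta(α/2; x, n−x+1)`,
  `qbeta(1−α/2; x+1, n−x)`), split into prevalent users (in polypharmacy at
  the index date) and incident users, with dementia and age-band
  (60–69 / 70–79 / 80+) subgroups;
* **bivariate and multivariable logistic odds ratios** `exp(β̂)` with Wald
  intervals `exp(β̂ ± z·SE)` for baseline factors, age-indicator coded
  against 60–69;
* **event composition tables**: class frequencies, class-combination
  frequencies per event and per-agent frequencies.

A seeded synthetic claims generator with known ground truth (latent logistic
propensity driving regimen construction) backs the test suite and makes
parameter recovery verifiable; see the methods vignette
(`vignettes/cns-polypharmacy.Rmd`).

## Worked example

```r
library(polypharm)

dir <- tempfile()
sim <- simulate_study(generator_config(n_patients = 5000, seed = 42), dir)
man <- run_pipeline(run_config(sim$paths$patients, sim$paths$fills,
                               file.path(dir, "out")))

prev <- readr::read_csv(file.path(dir, "out", "prevalence.csv"))
prev[prev$stratum == "overall",
     c("rule", "numerator", "denominator", "percent",
       "ci_low_pct", "ci_high_pct")]
#>           rule numerator denominator percent ci_low_pct ci_high_pct
#>  month_grace_1       373        5000     7.5        6.7         8.2
#>      same_week       287        5000     5.7        5.1         6.4
#>  month_grace_2       405        5000     8.1        7.4         8.9
```

373 of 5 000 synthetic patients have at least one month with ≥ 3 concurrent
CNS-active agents under the main rule — a 7.5% period prevalence (exact 95%
CI 6.7–8.2%). The no-grace week rule finds fewer affected patients and the
2-month grace more, and the three patient sets are provably nested. The run
also writes `association.csv`:

```r
#>     variable odds_ratio_bivariate odds_ratio_multivariable ci_low ci_high
#>  age_band80+                 2.12                     2.32   1.77    3.04
#>   depressive                 4.50                     4.27   3.35    5.44
#>     dementia                 3.65                     4.13   2.86    5.95
```

so e.g. a depressive-disorder diagnosis multiplies the odds of polypharmacy
by 4.3 (95% CI 3.3–5.4) after adjustment, against a generator truth of 3.5
(a single n = 5 000 draw; the recovery tests average 200 larger replicates).
The manifest reports 1 825 events involving 6 003 medication records among
the 373 patients (median 3 months from index to first event), and
`combinations.csv` starts with antidepressant + antipsychotic +
benzodiazepine as the most frequent class combination (6.7% of events).

The exact-interval arithmetic applies to any published counts directly:

```r
ci <- clopper_pearson(4535, 63857)
c(pct(4535 / 63857), pct(ci$low), pct(ci$high))
#> [1] 7.1 6.9 7.3
```

A thin CLI (`inst/scripts/polypharm`) exposes `simulate`, `validate` and
`run` subcommands over the same functions.

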