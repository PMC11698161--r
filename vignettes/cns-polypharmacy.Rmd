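---
title: "Measuring CNS-active polypharmacy from pharmacy claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring CNS-active polypharmacy from pharmacy claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(polypharm)
```

## The measurement problem

Concurrent use of three or more centrally acting medications — antidepressants,
anti-epileptics, antipsychotics, benzodiazepines, Z-drugs and opioids — is a
recognised safety problem in adults aged 60 and older: it is associated with
falls, cognitive decline, overdose and mortality, and clinical guidance (e.g.
the Beers criteria) advises against it. Pharmacy claims are the practical way
to measure it at population scale, but claims record *purchases*, not
ingestion, and typically carry no days-of-supply field. The analyst therefore
has to (i) decide which agents count as CNS-active, (ii) turn dated fills into
plausible exposure intervals, (iii) define what one "polypharmacy event" is,
and (iv) summarise the result as a period prevalence with honest uncertainty
and as associations with baseline characteristics. `polypharm` implements that
chain as composable, individually tested steps.

## The exposure model

Time is discretised: calendar months for the grace-period rules, ISO-8601
weeks for the no-grace sensitivity rule. The ISO convention is used because
"calendar week" is otherwise ambiguous across locales; determinism matters
more here than any particular week numbering. A fill of agent $a$ in month
$m$ makes the patient exposed to $a$ throughout months $[m, m+g]$, where the
grace period $g$ absorbs real-world refill behaviour — stockpiling, early or
late purchases. The package ships three rules:

* `month_grace(1)` — the main analysis: exposed through the fill month and
  one further month;
* `month_grace(2)` — sensitivity: two further months;
* `same_week` — sensitivity: exposed exactly in the fill's ISO week.

Per (patient, agent), overlapping or adjacent coverage is merged into maximal
intervals, so concurrency queries are simple interval containment. Coverage is
monotone in $g$ by construction, and any week with $k$ concurrently filled
agents implies a month with at least $k$ concurrent agents under
`month_grace(1)` — which is why the set of detected patients is always nested
across the three rules, before any data are seen.

A **polypharmacy event** is one patient-period (month or week) with at least
three *distinct* agents — distinct by full 7-character ATC code, so three
different benzodiazepines qualify while the same substance filled twice does
not. One period contributes one event carrying the entire concurrent set; a
patient can contribute many events. The period is the finest unit consistent
with the grid; an episode-level unit (maximal runs of consecutive event
periods) is a coarser alternative we considered and rejected because it makes
combination tallies ill-defined when the agent set changes mid-episode.

The ATC dictionary is a longest-prefix-wins rule table with full-code
overrides. The shipped default follows a strict antidepressant definition
(SSRI, SNRI, TCA); a permissive mode admits all of N06A (bupropion,
mirtazapine, trazodone, ...). Lithium (N05AN) is excluded from antipsychotics
by default since it is conventionally a mood stabiliser; a single override row
re-includes it. Every default is replaceable through a two-column CSV, so the
shipped table is a documented convention, not a hidden assumption.

## Prevalence and association estimates

Period prevalence is the number of distinct patients with at least one event
during the study year (the window includes the index month, so prevalent
users at index count) divided by the full index-date cohort — patients later
censored by death or disaffiliation stay in the denominator. Confidence
intervals are Clopper–Pearson exact intervals via the Beta-quantile endpoints
$\mathrm{qbeta}(\alpha/2;\,x,\,n-x+1)$ and
$\mathrm{qbeta}(1-\alpha/2;\,x+1,\,n-x)$; the test suite checks them against
an independent bisection on the binomial tail sums to $10^{-8}$, and verifies
the method's conservative coverage both exactly (summing binomial point
masses) and by simulation. Display percentages are rounded half-up to one
decimal; raw counts are always emitted alongside.

Associations with baseline factors use maximum-likelihood logistic regression
(`stats::glm`), bivariately and multivariably, reporting $e^{\hat\beta}$ with
Wald intervals $e^{\hat\beta \pm z_{1-\alpha/2}\,\mathrm{SE}}$. Age enters as
indicators with 60–69 as reference; prior-year admissions as a count. Because
the outcome mixes prevalent and incident users, these are exploratory
associations, not causal effects. Zero-variance covariates are dropped with a
warning; a zero cell in a bivariate 2×2 table and (quasi-)separation in the
multivariable fit are hard errors naming the covariate — no silent continuity
corrections. The pipeline pre-screens its default covariate list for empty
cells so that rare diagnoses do not abort a small-cohort run.

## What the synthetic generator emulates

Real claims of this kind are not publicly shareable, so the package includes
a generator whose ground truth makes every downstream estimate testable. It
emulates an HMO cohort of ~64 000 members aged 60+ observed 2017–2021 with a
1 January 2021 index date: mostly aged 70+, majority female, anxiety 21%,
depressive 14% and sleep disorders 11% as the leading mental-health
diagnoses, annual death and disaffiliation risks of 3.7% and 0.7% (censoring
stops fills but never removes a patient from the prevalence denominator).

The key design choice is that a patient-level latent logistic model —
intercept plus covariate log odds ratios — draws a ground-truth polypharmacy
indicator *first*, and fills are then constructed to realise it: every true
case receives a regimen of ≥3 distinct agents all filled together in the
first in-window month of their episode, while controls never exceed two
concurrent agents under the 1-month-grace rule. Detection under the main rule
therefore reproduces the latent truth exactly, which makes odds-ratio
recovery a well-posed estimation problem: the model the analyst fits is the
model that generated the outcome. The default depressive-disorder log-OR is
$\log 3.5$; across 200 replicates at $n = 20\,000$ the multivariable estimate
recovers it with mean error under 5% and ~95% Wald coverage.

Remaining behaviour is layered on top without breaking that identity:

* *prevalent users* (26.7% of cases) have episodes anchored at the index
  month with pre-index fills;
* *incident* first-event months decay geometrically (rate 0.92), giving a
  median of 3 months (IQR 0–6) from index to first event;
* *refills* occur with monthly probability 0.85, thinned by a stockpiling
  probability of 0.12 (double boxes the month before, no fill that month) —
  gaps the grace period is designed to absorb;
* *pharmacy-visit batching*: with probability 0.4 all of a patient-month's
  fills happen on one visit day, which governs how many events the no-grace
  same-week rule can see (~73% of main-rule cases, matching the relative
  magnitude of week-rule to month-rule prevalence);
* *switchers* (0.7% of controls) stop two agents two months before starting
  a third: their single triple-concurrency month is visible only under the
  2-month grace, so the rule ordering week ≤ 1-month ≤ 2-month is strict;
* *background users* (25% of controls) fill one or two CNS agents, and
  everyone accrues non-CNS noise fills, exercising the dictionary filter.

The intercept (−3.8558) was calibrated once by Monte Carlo so the marginal
event probability is 0.071 under the default covariate mix; episode duration
(mean 6 months) reproduces ~5 events per affected patient and ~3.3
medications per event. All of this is configurable; `ground_truth()` reports
the generating values for any configuration.

What the generator does **not** emulate: dose or days-of-supply (the source
registry lacks them), in-hospital dispensing, diagnosis-code noise, secular
trends, or any misclassification of the outcome. Passing tests therefore
demonstrate that the *pipeline arithmetic* is correct under the stated
exposure model, not that the exposure model itself is clinically unbiased for
any particular real registry.

## Numerical choices and degenerate inputs

* Date-period conversion is pure integer arithmetic (months since year 0,
  ISO weeks since the Monday 1970-01-05), a bijection tested day-by-day over
  the whole window.
* Quantiles for time-to-first-event use `quantile(type = 7)` (linear
  interpolation), stated because median/IQR conventions differ.
* Logistic fits run IRLS to a $10^{-10}$ deviance tolerance; coefficients
  with $|\hat\beta| > 15$ on the logit scale are treated as separation.
* Empty fill tables, empty event sets, all-event and no-event cohorts, and
  zero-patient configurations all return well-formed empty or boundary
  results rather than erroring.
* RNG is R's default Mersenne-Twister; a single integer seed determines the
  cohort and the fill stream, and two runs with one seed are byte-identical.

Test problem sizes were chosen so the full suite exercises cohorts up to
20 000 patients and 200-replicate recovery studies; the published cohort's
arithmetic (4 535 / 63 857 and its exact interval) is reproduced directly
from the counts, which is an $O(1)$ computation at any scale.

## Known limitations

The event unit is a patient-period, so a long uninterrupted episode counts
once per month; analyses that need episode counts should merge consecutive
event periods themselves. The distinctness criterion is the 7-character ATC
code: combination products or the same substance under two codes count as
distinct agents. The generator's controls are structurally incapable of
triple concurrency under the main rule — convenient for testability, but it
means false-positive behaviour of the detector cannot be studied with the
default generator; inject custom fill tables for that.
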