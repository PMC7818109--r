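---
title: "Markov cohort cost models of programs delaying residential aged care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov cohort cost models of programs delaying residential aged care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pracdelay)
```

## The model

`pracdelay` implements three-state Markov cohort cost models for community
support programs aimed at older people living with dementia or cognitive
impairment. Two programs are bundled as default specifications: a 5-day
residential dyadic carer-training program (GTSAH, one-off cost $3,755 per
dyad) and a 12-month interdisciplinary frailty-rehabilitation intervention
(FIT, one-off modelled cost $1,834). Each is compared against standard care
(home care packages, standard medical services and respite).

The state space is fixed: **Community**, **permanent residential aged care
(P-RAC)** and **Death**. The whole cohort enters in Community. Each monthly
cycle a person in Community may be admitted to P-RAC (probability $p_a$ per
month) or die (probability $q_c$); P-RAC residents may only die ($q_p$);
Death is absorbing and accrues nothing. There is no return from P-RAC to
the community and no high/low P-RAC distinction (that split is no longer
used in the Australian aged care system). Within a cycle, death is applied
first and admission applies to survivors, so the Community row of the
transition matrix is

$$\big((1-q_c)(1-p_a),\; (1-q_c)\,p_a,\; q_c\big).$$

Alternative orderings differ at $O(q_c p_a)$ — about $10^{-3}$ relative on
the default inputs — and would be an equally defensible convention; the
death-first form keeps rows stochastic without renormalisation.

The base case runs 60 monthly cycles (5 years) and discounts at 5% per
annum, compounded continuously in the exponent:
$d(t) = (1+r)^{-t/12}$ for $t$ in months. This is exact at annual
boundaries and is the convention of Australian health-economic guidance.
Each cycle's accrual is discounted at its cycle-end time, consistent with
the half-cycle correction below.

## Cost accrual

While in Community the cohort accrues the program cost (intervention arm
only, once at cycle 0, undiscounted and without half-cycle correction) plus
recurring monthly costs for hospitalisation, respite residential aged care,
home care packages, GP and allied-health visits. In P-RAC it accrues the
accommodation cost — $237 per day, converted with the calendar-average
365.25/12 ≈ 30.44 days per month — plus hospitalisation, clinician
attendances and pharmaceuticals. All costs are 2018 AUD per modelled
person.

Recurring costs use trapezoidal half-cycle correction: the accrual weight
for state $s$ in cycle $t$ is the average of the cycle-start and cycle-end
occupancies. The one-off program cost is exempt; the structure of the
published sensitivity rows supports this (halving the intervention cost
moves the intervention arm's total by exactly half the program cost, which
only happens if the program cost carries no discounting or half-cycle
weight), and the package's scenario tests assert the same exact shift.

Break-even is the first cycle at which the intervention arm's cumulative
discounted cost no longer exceeds standard care's; a tie counts, and the
result is reported in months (cycle index × cycle length).

## Mortality

Annual death probabilities come from a life table (CSV with columns
`age,annual_death_prob`; ages at or past `max_age` are treated as certain
death, ages between rows use the floor-age row as annual actuarial tables
do). The monthly probability applies dementia excess mortality and
per-state multipliers on the hazard (log-survival) scale:

$$q_{\text{month}} = 1 - \exp\!\big(\log(1-q_{\text{annual}})\cdot
\mathrm{RR}\cdot m_s / 12\big).$$

The hazard scale keeps probabilities in $[0,1]$ for any relative risk;
multiplying probabilities directly can exceed 1 and is rejected. With
RR $= m_s = 1$ the twelve compounded monthly probabilities recover
$1-q_{\text{annual}}$ exactly. The cohort is modelled at a single
representative start age, matching the use of "cohort age" as a scalar
scenario lever; mortality is identical across arms.

## Parameters and defaults

Published anchors used by the default specs: monthly admission
probabilities 0.05 (standard care) vs 0.02 (intervention) for the GTSAH
model and 0.03 vs 0.01 for the FIT model (the latter derived from 12-month
proportions 9/29 and 2/19 by the constant-hazard conversion
$1-(1-p)^{1/12}$); program costs $3,755 and $1,834; P-RAC at $237/day; 5%
annual discounting; 60 monthly cycles.

Everything else a runnable model needs was published only in supplementary
material and is filled in by documented synthetic values, centralised in
`synthetic_constants()` and marked SYNTHETIC so no test mistakes them for
published inputs:

| parameter | default | units | note |
|---|---|---|---|
| cohort start age | 78 (GTSAH) / 83 (FIT) | years | plausible for the two study populations |
| dementia mortality RR | 2.0 | hazard ratio | configurable |
| life table | Gompertz $a=5\times10^{-5}$, $b=0.095$, ages 60–110 | annual $q$ | $q(a) = 1-\exp(-a e^{b\,\text{age}})$, monotone increasing |
| community costs | hospitalisation 400, respite 150, HCP 1,200, GP 60, allied health 80 | AUD/person-month | order-of-magnitude realistic; P-RAC accommodation (~$7,214/month) dominates regardless |
| P-RAC extras | hospitalisation 150, clinician 100, pharmaceuticals 120 | AUD/person-month | |

Because the community resource intensities are synthetic, the default
specs reproduce the *structure* of the published analysis — signs,
orderings, break-even existence, exact program-cost arithmetic — not its
absolute dollar totals, and the tests are written accordingly. The
12-month proportion conversions and the national budget-impact arithmetic
*are* fully determined by printed inputs and are checked at printed
precision.

## Sensitivity scenarios

`apply_scenario()` applies named edits (`multiply`/`set`/`add` on
dot-separated parameter paths) to a spec, purely and composably;
multivariate scenarios are sequences of univariate edits. The packaged
scenario file (`default_scenarios()`, 25 scenarios) covers time horizon (1,
3, 7 years), discount rate (0%, 10%), halving/doubling of intervention,
hospital, P-RAC and respite costs and of home-care-package use, the
admission-probability difference, cohort age ±10 years, dementia excess
mortality, doubled P-RAC mortality, and three combinations.

Two genuinely open design points, decided as follows:

* The *admission-probability-difference* lever holds the standard-care arm
  fixed and rescales the gap: $p'_{\text{int}} = p_{\text{sc}} -
  k\,(p_{\text{sc}} - p_{\text{int}})$, clamped to $[0,1]$. The published
  halved-difference rows keep the standard-care totals unchanged, which is
  consistent with this choice. For the doubled GTSAH gap the formula gives
  $0.05 - 0.06 < 0$ and clamps to 0 (the published table appears instead
  to have raised the standard-care arm for that one infeasible row; the
  clamp is this package's documented convention).
* "Mortality doubled for people in P-RAC" doubles the P-RAC hazard
  multiplier; "excess mortality doubled/halved" scales the dementia RR,
  both on the hazard scale.

On both default specs every one of the 25 scenarios leaves the
intervention cost-saving, and savings magnitudes order as expected:
growing with P-RAC cost, horizon and the probability difference, shrinking
with their halved counterparts and with a higher discount rate.

## Budget impact

`budget_impact()` scales per-person quantities linearly to an eligible
population (central estimate with ±10% bounds, bounds rounded to the
nearest 100 persons — 31,800 → 28,600/35,000 and 158,900 →
143,000/174,800). Money columns are also reported in millions rounded
half-up, the convention that reproduces the published national table
(e.g. 31,800 × $11,248 = $357.7M → 358). One known discrepancy: 174,800 ×
$1,834 = $320.58M rounds to 321 while the published table prints 320; the
package keeps the honest rounding rather than special-casing that cell.
Admissions delayed are computed from cumulative Community→P-RAC flows
(`per_person_results()`), not horizon occupancy, because occupancy
undercounts people who enter P-RAC and die before the horizon.

## Subgroup statistics

For the cognitively impaired FIT subgroup the package provides exact 2×2
tests and t tests. Fisher's exact test is implemented directly from
hypergeometric densities: the one-sided p is the tail in the direction of
the observed deviation from the conditional expectation; the two-sided p
uses the point-probability rule. For the high-level-care comparison (0/19
vs 6/29) the one-sided tail is 0.0387, which prints as 0.04 at two
decimals; the two-sided value is ≈ 0.068. The published report does not
state sidedness, so both are exposed and neither is asserted as the
original intent. Chi-square and t tests delegate to `stats::chisq.test()`
and `stats::t.test()` behind the module interface; the chi-square wrapper
refuses tables with a zero expected cell and points to Fisher's test.

## Synthetic data and validation

The synthetic-data module generates every input the analysis needs without
downloads: Gompertz life tables, the two default specs, per-participant
subgroup records (binary 12-month admissions plus total care days from a
zero-inflated lognormal whose mixture moments are solved to match a target
mean/SD — feasible only when $p \ge \mu^2/(\sigma^2+\mu^2)$, otherwise an
error), and an individual-level microsimulation. All randomness flows from
an explicit seed argument through a local RNG state; the caller's global
RNG is restored on exit.

The microsimulation is the package's independent oracle for the
deterministic engine: each of $n$ individuals walks the same per-cycle
transition matrices and accrues the same half-cycle-corrected discounted
costs, so mean occupancy, mean cumulative admissions and mean cost
converge to the cohort-trace values. The equivalence suite compares engine
and microsimulation on five randomised specifications at $n = 200{,}000$
individuals each. Because that makes 25 simultaneous fixed-seed
Monte-Carlo comparisons, each is tested at a Bonferroni-adjusted 3-sigma
level (critical value ≈ 3.8) so the whole family retains the false-alarm
probability of a single 3-sigma check; a genuine engine bias of even 0.5%
absolute would exceed 9 sigma at this $n$, so the adjustment costs no
practical power. Problem sizes throughout the test suite (200,000-person
simulations, 300-seed moment checks, 60-cycle horizons) were chosen as the
package's own accuracy/runtime balance; the full suite runs in well under
a minute of simulation time.

What the synthetic defaults do *not* emulate: real Australian life tables
(sex, calendar trends), heterogeneous cohort age mixtures, observed
community resource-use intensities, or correlation between admission and
care-day outcomes at the individual level. Passing tests therefore
demonstrate correctness of the modelling machinery and of every
printed-input computation, not calibration of absolute cost totals to the
original cohorts.

## Numerical conventions, edge cases, limitations

* Probability/rate conversions refuse $p = 1$ (infinite hazard); the
  Gompertz generator caps $q$ just below 1 with a warning and relies on
  the `max_age` rule for certain death.
* A cohort outliving its life table faces probability-1 death from
  `max_age` onward; validation rejects start ages below the table.
* Tie-break at break-even: equality counts as break-even; identical arms
  with zero program cost break even at cycle 1.
* Scenario edits that would push the intervention admission probability
  outside $[0,1]$ are clamped; an edited horizon below 1 cycle is an
  error.
* Deterministic scenario analysis only — no probabilistic sensitivity
  analysis, no QALYs or utilities, no productivity costs, no
  time-to-admission survival modelling, and no derivation of
  eligible-population estimates (they enter as parameters).
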