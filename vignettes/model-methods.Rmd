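---
title: "Model structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mtcea` implements a quarterly-cycle Markov state-transition model of three
management strategies for US adults presenting with a symptomatic meniscal
tear (MT) in the presence of knee osteoarthritis (OA): physical therapy alone
(`PT`), PT followed by arthroscopic partial meniscectomy for subjects still
in moderate pain after the first quarter (`delayed_apm`), and APM as
first-line treatment (`immediate_apm`). This vignette is the package's
account of the model itself: the health-state structure, the transition
logic, the economic accrual rules, the probabilistic machinery, and the
places where the design was genuinely open and a choice had to be made.

## Health states and cohort

A living subject is described by five coordinates:

* **pain** — low vs moderate, the dichotomised knee-pain status (KOOS Pain
  above 25 is "moderate"); utilities 0.869 (low) and 0.771 (moderate) per
  quarter-year of life, 0 when dead;
* **KL grade** — radiographic OA severity grouped as KL 0–1, KL 2, KL 3,
  KL 4 (absorbing);
* **TKA status** — native knee, or quarters since total knee arthroplasty
  (capped at five, which separates the first prosthesis year from later
  years);
* **consecutive moderate-pain quarters** — counted only after the initial
  three-month treatment period and capped at the TKA-eligibility gate of
  two quarters (six months);
* **prior APM** — a flag that exists so a structural-progression penalty
  can be applied to operated knees in sensitivity analyses.

The entry cohort is all-moderate-pain with mean age 58 (SD 7), truncated to
45–75, and KL shares 44.8 / 26.4 / 28.8 / 0 %. End-stage (KL 4) knees at
entry and subjects under 45 are deliberately out of scope. In cohort mode
the age distribution is discretised into six five-year bands with
truncated-normal weights and the model is evaluated as an exact expectation
per band; in microsimulation mode individual ages are sampled continuously.

## Quarterly transition logic

Events within a quarter are applied in a fixed order: background death (with
any peri-operative and pharmacologic excess mortality), structural KL
progression, treatment or TKA election, pain update, then accrual. The
evidence sources are silent on within-cycle ordering; this order is fixed in
code and shared by both engines.

* **Quarter 1 (months 0–3).** The index treatment is given (APM in the
  immediate strategy, PT otherwise). The end-of-quarter pain state is one
  Bernoulli draw from the treatment's *failed pain relief* probability,
  stratified by KL band (0–2 vs 3–4).
* **Quarter 2 (months 3–6).** Subjects relieved at three months face the
  treatment's pain-*incidence* probability; unrelieved subjects face one
  minus its pain-*resolution* probability. In the delayed strategy, every
  subject still in moderate pain crosses over to APM with probability one
  and instead faces the single APM-after-PT failed-relief draw; the
  crossover context has no months-3-6 window of its own (its incidence and
  resolution entries are zero).
* **Beyond month 6.** Pain changes are attributed to the underlying OA
  only: annual incidence/resolution by KL grade converted to quarterly
  probabilities. By construction these probabilities depend only on
  (KL, pain, TKA status), never on the original treatment arm.
* **Structural progression.** One grade step at most per quarter: age-banded
  annual OA incidence for KL 0–1 knees, 0.0735 / 0.0267 annually for
  KL 2→3 / KL 3→4. The base case assumes APM does not influence
  progression; `apm_progression_multiplier` scales the two progression
  rates for operated knees in the two-way sensitivity analysis and is
  clamped (with a warning) if a product exceeds one.
* **TKA.** Subjects with a native knee, KL 3–4, and at least two counted
  consecutive moderate quarters may elect TKA at the age-banded annual
  uptake rate (0.064 / 0.119 / 0.030, quarterly-converted). The earliest
  possible replacement is therefore quarter 3, after six months of
  post-treatment pain. Post-TKA pain is redrawn each quarter: probability
  0.862 of low pain during the first prosthesis year, 0.960 thereafter —
  the published "annual efficacy" values are ambiguous between *attaining*
  and *being in* relief; they are implemented as the per-quarter probability
  of occupying the low-pain state, which makes the two readings coincide in
  occupancy terms. One TKA per subject; no revisions.
* **Mortality.** Annual all-cause death probabilities at `floor(age)` come
  from a bundled life table and are quarterly-converted. The packaged table
  is a *synthetic* Gompertz approximation calibrated to published 2009 US
  all-cause anchor points (it is not the official intercensal table, which
  cannot be redistributed here); any CSV with columns
  `age, annual_death_prob` can be substituted. Excess mortality: APM
  0.015 × 0.011 in the surgery quarter, TKA 0.036 × 0.006 at election, and
  pharmacologic pain management 0.111 (annual, quarterly-converted) × 0.005
  per moderate-pain quarter. The pharmacologic event denominator is not
  stated in the source evidence; per-year-of-exposure is assumed.

All annual-to-quarterly conversions use the constant-hazard form
$p_q = 1-(1-p_a)^{1/4}$. No half-cycle correction is applied: cycles are
short relative to the horizon, and each quarter accrues the state occupied
at its start, so first-order timing error is bounded by one quarter.

## Accrual rules

QALYs and costs are discounted at 3 % per year on a quarterly grid,
$(1+r)^{-(t-1)/4}$ for quarter $t$; the ten-year base horizon is 40 cycles.

**Direct medical costs** (2013 USD). Treatment bundles are charged once, in
the quarter of use: the PT bundle ($209 healthcare + $568 rehabilitation)
in quarter 1 of the PT-first strategies; the APM bundle ($2,867 procedure +
$454 post-operative healthcare + $439 rehabilitation + expected
complication cost 0.015 × $11,589) in quarter 1 of the immediate strategy
and, for crossovers, in quarter 2 of the delayed strategy weighted by the
crossover fraction. Whether PT rehabilitation recurs for persistent-pain PT
subjects is not stated in the evidence; a single bundle is assumed.
Pain-management costs accrue every quarter by pain state ($276 moderate,
$99 low), including after TKA, plus the expected pharmacologic complication
cost (quarterly event probability × $1,816) in moderate quarters. TKA
charges $20,282 plus the expected complication cost 0.036 × $15,149 at
election.

**Productivity (time) costs** are a sensitivity analysis, excluded from the
base case. Hours lost per quarter are phase- and state-specific: months 0–3
of treatment (APM 109 h, PT 79 h), months 3–6 (87 h moderate / 42 h low),
thereafter 70 h / 30 h, all valued at $22.33/h. Two modelling choices here
deserve emphasis:

* *Phases are anchored to the index treatment*, matching the table's own
  phase definitions and the six-month treatment-attribution window: a
  delayed-strategy crossover operated at month 3 draws surgery-phase hours
  in calendar quarter 2 and months-3-6 hours in calendar quarter 3.
* *The employment adjustment is relative, not absolute.* The published
  hours are already weighted averages over employed and unemployed
  subjects at entry (about 60 % employed); the age schedule only *adjusts*
  them for the declining likelihood of employment. The engine therefore
  multiplies hours by `employment(age)/employment(entry age)`, with a
  piecewise-linear schedule flat at 0.60 to age 58 and declining to 0.10
  at 70. Treating the schedule as an absolute multiplier would double-count
  baseline unemployment and understate ten-year time costs by roughly a
  third.

## Probabilistic sensitivity analysis

Only the starred quantities of the parameter table carry distributions:
the twelve non-degenerate treatment-phase pain probabilities are
`Beta(events, non-events)`; six cost and six hour quantities are
`Gamma(alpha, lambda)`. Everything else — utilities, OA pain dynamics,
progression, uptake, efficacy, adverse-event rates, procedure costs — is
fixed. Draws are independent: no correlation structure is asserted by the
evidence. For several gamma rows the distribution mean `alpha/lambda`
disagrees with the published point estimate (e.g. $258 vs $276 for
moderate-pain management); both are retained — the base case uses the
published means, PSA draws come from the distributions — and
`dist_gamma()` warns when the gap exceeds 5 %. Deterministic and
probabilistic mean results therefore differ slightly by design.

One master seed drives an analysis; iteration *i* uses the deterministic
`child_seed(master, i)`, so any single PSA iteration can be reproduced in
isolation via `sample_psa()`. Within an iteration all three strategies share
the same draw, preserving the between-strategy correlation that the
acceptability analysis depends on.

Because none of the sampled parameters enter the post-month-6 dynamics, the
cohort engine shares its late-phase transition matrices across all PSA
iterations and propagates an iterations × states occupancy matrix through
them; 10,000 iterations of all three strategies complete in well under a
minute on one core.

## Decision analysis and value of information

The ICER ladder (`icer_table()`) sorts by cost, removes strong dominance
(weak convention: an exact duplicate is dominated), iteratively removes
extended dominance until frontier ICERs increase, and reports adjacent
ICERs. `ceac()` reports, per willingness-to-pay threshold, the fraction of
iterations in which each strategy attains the highest net monetary benefit
(`wtp × QALYs − cost`), splitting exact ties equally — a measure-zero event
for continuous draws, but the convention matters for degenerate inputs.
`ceaf()` follows the conventional frontier definition: the strategy with
the highest *mean* NMB at each threshold, reported with its CEAC value.
(The alternative reading — the strategy most often best — crosses at
nearly the same threshold for the PT-to-delayed switch in this model but
much later for the delayed-to-immediate switch.)

EVPI is `mean(max NMB) − max(mean NMB)` over the PSA. EVPPI uses an
assumption-free nested two-level Monte Carlo estimator (outer draws fix the
parameter group, inner draws integrate the complement), floored at zero;
the regression-free choice is deliberate, since the estimator is itself a
validation target against closed-form toy problems in the test suite.
Nested MC is quadratic in cost, so the reporting default (100 × 200) is
far below the 500 × 500 a production EVPPI analysis would use. The
`apm_progression` group carries no distribution in the default
configuration, so its EVPPI is zero by construction. Population VOI scales
per-person EVPI by 352,000 persons facing the decision annually over a
three-year usable life of information, discounting successive cohorts at
3 %.

## Synthetic trial generator

`generate_trial()` emulates the *statistical structure the model's
first-year parameters assume*: KL strata from the cohort shares, Bernoulli
3-month outcomes per arm × KL band, 6-month outcomes from the
incidence/resolution probabilities (with the crossover arm applying PT
first-quarter probabilities, then the APM-after-PT draw to 3-month
failures), gamma-distributed quarterly costs and hours, and Bernoulli
employment at 60 %. `estimate_from_trial()` inverts it: beta distributions
from stratum counts and gamma fits by method of moments
(`alpha = m²/v`, `lambda = m/v`), flagging empty strata and zero-variance
samples as unestimable rather than filling them.

What passing recovery tests do and do not show: the generator contains no
dropout, no measurement error, no within-subject correlation between cost
and outcome, and no covariates beyond the KL band — so parameter recovery
at n = 10⁵ demonstrates that the estimation path is consistent for the
assumed data-generating process, not that the pipeline is robust to the
messiness of a real trial export.

## Numerical choices and problem sizes

* Cohort occupancy is checked to sum to one every quarter (tolerance
  1e-10 in tests; observed error is at machine precision).
* Ages below the life-table floor raise an error; ages beyond its cap use
  the final row.
* Ties in the cost ordering of `icer_table()` are broken by descending
  QALYs; exact duplicates fall to the dominated set.
* The test suite exercises the documented study sizes directly: 10,000 PSA
  iterations for acceptability and EVPI checks, 50,000 subjects for the
  microsimulation-vs-cohort equivalence (agreement within three standard
  errors for QALYs and direct costs; time costs agree to ~1 %, the residual
  being the deliberate entry-age banding of the employment schedule in
  cohort mode), and 10⁵ subjects per arm for parameter recovery.
* EVPPI validation uses a two-strategy toy problem with normal NMB, whose
  information value has the closed form `sd/√(2π)`.

## Known limitations

* The bundled life table is a smooth synthetic approximation; absolute
  mortality above age ~85 is slightly understated relative to official
  tables, which is immaterial over a ten-year horizon from age 58 but
  matters if the model is re-aimed at older cohorts.
* Sex-specific mortality and employment are not modelled (the cohort's sex
  split is not available); a single pooled schedule is used.
* Costs are 2013 USD throughout; no inflation machinery is provided.
* The delayed-vs-PT incremental cost is the quantity most sensitive to the
  bundling assumptions above; its reproduction sits near the edge of its
  published band, and the frontier switch point it induces (~$17–18k)
  overshoots the published ~$13k.
* EVPI reproduces at roughly three-quarters of the published per-person
  value — within the factor-of-two band that re-implementations of
  information value can realistically achieve, but users comparing absolute
  VOI figures should expect that scale difference to propagate to the
  population estimates.
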