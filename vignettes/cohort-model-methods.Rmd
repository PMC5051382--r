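---
title: "Methods: a lifetime cohort state-transition model for cardiovascular risk interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lifetime cohort state-transition model for cardiovascular risk interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdcea)
```

## The decision problem

Trials of interventions that lower cardiovascular disease (CVD) risk —
blood-pressure management, weight management, telehealth-supported
behaviour change — typically follow participants for about a year, while
the benefit of a lower risk score accrues over decades, as avoided heart
attacks and strokes. `cvdcea` bridges that gap with an annual-cycle cohort
state-transition (Markov) model: trial-level inputs (ten-year risk scores
per arm at baseline and at 12 months, year-0 NHS costs and QALYs) are
extrapolated over the remaining lifetime of the cohort, and the
incremental cost per quality-adjusted life year (QALY) of the intervention
is evaluated under alternative assumptions about how long its effect on
risk persists.

## Model structure

Health states are defined by the events a ten-year CVD risk score
predicts: a single CVD-free state; acute states for acute myocardial
infarction (AMI), stable angina, unstable angina, transient ischaemic
attack (TIA) and stroke; post-event states (post-AMI, post-TIA,
post-stroke); and two absorbing death states (CVD death, non-CVD death).
Pure acute states last exactly one cycle and then hand over to their
post-event state, which mirrors the first-year/subsequent-year costing of
the health-technology-assessment models this structure descends from. The
angina states have no separate post-event counterpart: they are chronic,
acting as their own post-event destination, so an angina cost and utility
decrement recur annually. A consequence of collapsing the acute and
chronic angina years into one state is that angina states are exposed to
secondary events in every cycle, including the first.

Simulated patients experience at most three CVD events over a lifetime.
The computational state space is therefore the clinical state crossed with
a lifetime event count (0–3): entering any acute state increments the
count; moving from an acute state to its post-event destination does not.
At the cap, only persistence and death remain. The reachable expanded
space under the default topology has 27 states. The registry of states and
permitted transitions is data, not code (`state_registry()`), so
alternative topologies can be supplied; whether repeat events may chain
directly from an acute state within one cycle is unresolved in the source
models, and the default routes all repeat events through post-event (or
chronic) states.

Cohorts enter CVD-free, cycle annually until death, and die with certainty
at age 100. Cohorts are stratified by trial arm and sex (80% male; entry
at the mean trial ages of 67 for men and 69 for women); an optional mode
spreads each stratum over a discretized truncated-normal age distribution
for sensitivity work.

## Risk trajectories

Year-0 risk is the arm's mean baseline ten-year score; year-1 risk is the
12-month score adjusted for baseline. Later years grow the score
multiplicatively by a male age-specific growth rate (one value per year of
age, exact lookup — the growth table derives from evaluating a risk score
at integer ages, so interpolation would be spurious). Female paths reuse
the male growth table: female risk then stays below male risk at all ages
and the extrapolation remains plausible. Beyond age 84, where ten-year
risk scores are not validated, the score grows by one percentage point per
year — the slope of an ordinary least-squares regression of score on age.
Whether that "1% per annum" is additive or relative is ambiguous; both are
implemented (`elderly_growth`), additive is the default, and each rule is
isolated in one branch so alternates are one-line swaps. Risk is capped at
1 throughout.

A duration-of-effect scenario of `D` years keeps the intervention arm on
its own (lower) risk path for model years 1..`D`; in year `D + 1` risk is
the average of the two arms' paths, smoothing the jump when the effect
expires; afterwards the intervention arm follows the control path. The
smoothing year is read as the first post-effect year. A lifetime duration
keeps the intervention path permanently. Year 0 is never modified, since
year-0 outcomes are trial observations.

Ten-year risk converts to an annual any-event probability by the
constant-hazard complement `1 - (1 - R10)^(1/10)` — the conversion formula
is not dictated by the source material; this is standard
decision-modelling practice and order-preserving. The annual probability
splits into event-specific probabilities by age-band- and sex-specific
incidence shares that sum to one.

## Transitions and mortality

Within a cycle, competing risks are ordered: non-CVD death first (life
table times a non-CVD standardised mortality ratio, SMR, which excludes
CVD causes of death), then CVD dynamics conditional on survival. From the
CVD-free state the event-specific probabilities apply, each split by an
age- and sex-specific case-fatality proportion into a fatal part (directly
to CVD death, at the event cycle) and a non-fatal part (to the acute state
with count incremented). Post-event and chronic states face
secondary-event probabilities with the same fatal/non-fatal split;
residual mass persists. This ordering guarantees stochastic rows without
rescaling; if event probabilities conditional on survival would exceed 1,
construction fails loudly rather than silently rescaling. Simultaneous
events within a cycle are excluded.

## Valuation, half-cycle correction, discounting

Utilities are multiplicative: an age- and sex-specific population EQ-5D
norm (the standard published quadratic regression in age, evaluated at
band midpoints) times a state-specific multiplier, assuming a constant
proportional effect of each condition on baseline utility. The unstable
angina multiplier is 90% of the stable angina multiplier, and post-event
multipliers are never below their acute event's, both as structural
constraints on inputs and as a post-draw adjustment in the PSA. Second and
third events reuse first-event utilities (values attach to states, not
event ordinals). Costs are per-state annual amounts; the CVD-free state
costs nothing beyond year 0.

Costs and QALYs accrue with a trapezoidal half-cycle correction: cycle `t`
accrues on the average of the occupancy at its start and end, which is the
standard half-cycle correction and treats costs and outcomes identically.
On an alive/dead toy model with death probability `p` this yields a life
expectancy of exactly `1/p - 1/2`, which the test suite checks to 1e-9.
Discounting is 3.5% per year, with cycle `t` discounted by
`(1.035)^-t`. Year 0 is undiscounted and entirely replaced by the
trial-observed year-0 costs and QALYs per arm (which include the
intervention cost); simulated dynamics start contributing at cycle 1.
Whether the source analysis discounted year 0 is not stated; treating the
trial year as undiscounted is the natural reading of using observed
12-month outcomes as-is.

## Probabilistic sensitivity analysis

Each of 1000 iterations draws one joint parameter set shared by both arms
and all scenarios (common random numbers; only the intervention effect
differs between arms, which isolates the intervention signal): costs from
gamma distributions moment-matched to mean and standard error (`shape =
(mean/se)^2`), utility multipliers and the SMR from univariate normals
(utilities clamped to [0, 1]), and the year-0 between-arm increments from
normals. Incidence shares, secondary transition probabilities and case
fatality are fixed — no uncertainty distributions are stated for them in
the source material — with Dirichlet/beta sampling left as an extension.
Risk scores are likewise not sampled, because the variance structure of
the underlying risk algorithm is unpublished; CEAC curves are accordingly
somewhat narrower than full parameter uncertainty would imply.

A parameter with a zero standard error is treated as exactly fixed and
consumes no random numbers, so the all-degenerate PSA reproduces the
deterministic (mean-parameter) run bit for bit — a property the tests
assert.

Because only the SMR draw affects transition probabilities, the CVD core
of every cycle's transition matrix is compiled once per run and mixed with
the sampled mortality scalar per iteration; cost and QALY accumulation
reduces to inner products with per-state discounted occupancy weights.
A test verifies this fast path agrees with the audit-grade route
(`build_cycle_table()` → `run_trace()` → `accumulate()`) to 1e-9.

## Decision metrics

Per scenario the summary reports mean per-arm discounted costs and QALYs,
mean increments with 95% intervals, the ICER of the mean increments
(ratio of means — the only convention consistent with reporting per-arm
averages), net monetary benefit `λΔQ − ΔC`, the probability of
cost-effectiveness (fraction of iterations with positive NMB) on a
threshold grid of £0–£50,000 per QALY in £500 steps always including
£20,000 and £30,000, and cost-effectiveness-plane quadrant shares
(axis-exact points go to the costlier/less-effective side). Interval
construction for increments is not fully specified in the source
material, and its printed incremental-cost intervals are far narrower
than its NMB intervals; both percentile-across-iterations and
SE-of-the-mean intervals are therefore computed and labelled, with
percentile as the headline. The discrepancy is noted, not resolved.

## The synthetic input generator

Published headline results depend on supplementary parameter tables and
individual-level trial data that are not redistributable; the generator
(`generate_cohort_strata()`, `generate_parameter_set()`) provides a
complete, internally consistent stand-in so the whole pipeline runs and is
testable with no downloads. Trial-level quantities that are printed —
arm/sex risk scores, 80% male, mean ages, the +£138 and +0.012 QALY year-0
increments, the 3.5% discount rate, the 90% unstable/stable angina ratio —
are reproduced exactly. Everything else is a documented plausible default
tagged `synthetic-default`: state costs (acute > post > CVD-free) and
utility multipliers in the range of published CVD cost and utility
reviews; a Gompertz-shaped life table; a non-CVD SMR of 0.78 (se 0.04),
reflecting that excluding CVD causes removes roughly a quarter of
all-cause mortality at these ages; incidence mixes that shift from AMI
towards stroke with age; secondary-event risk rising with age; and year-0
increment standard errors (£20 on cost, 0.0045 on QALYs) chosen so the
implied uncertainty on year-0 net benefit at £20,000/QALY (≈£92 SE)
matches the scale of the reported within-trial interval. Control-arm
absolute year-0 cost (£500) and QALYs (0.77) are configurable constants;
only the increments drive incremental results.

These stand-ins make no claim to match the unpublished tables: absolute
per-arm costs and QALYs are therefore only of the right order, while the
structure of the results — increments, their ordering across durations of
effect, the monotone CEAC family — is the meaningful output. Each table
can be replaced by transcribed real values per file via
`write_parameter_set()` / `load_parameter_set()` without touching code.

## Validation strategy

Two independent estimators of the same estimand are implemented: the
cohort trace (probability-weighted expectations) and an individual-level
microsimulation that samples paths through the identical per-cycle
transition matrices and applies the identical trapezoidal weights,
discounting and year-0 override. The acceptance tests require agreement
within three Monte-Carlo standard errors at 50,000 individuals, alongside
mass conservation of every trace under 100 random draws, the closed-form
toy-model life expectancy, exact-zero increments under a null
intervention, bit-for-bit degeneracy of the zero-SE PSA, CEAC limit
identities, and the monotone ordering of cost-effectiveness in the
duration of effect at the default study conditions (1000 iterations,
fixed seed).

## Problem sizes and numerical choices

Default runs simulate horizons of 33 years (men) and 31 years (women) over
27 expanded states, 1000 PSA iterations, four scenarios; a full run takes
well under a minute on one core. Transition-row sums are validated to
1e-10 (construction fails beyond 1e-8); trace conservation is asserted to
1e-8 on a cohort of 1000. Ties and degenerate cases have documented
conventions: ICER labels for dominance and indifference, signed-infinity
labels for zero QALY differences, plane assignment of axis-exact points,
and a hard failure (never rescaling) for probability overload.

## Known limitations

The model inherits the limitations of its design: no within-cycle event
timing beyond the half-cycle convention, no tunnel states beyond the
single acute year, annual cycles only, no value-of-information analysis,
risk-score uncertainty not propagated, and synthetic default inputs whose
absolute levels are placeholders. Passing tests demonstrate internal
consistency and faithfulness of the mechanics, not agreement with any
particular published cost or utility table.
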