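# cvdcea

Lifetime cost-effectiveness of cardiovascular-risk interventions by
cohort state-transition simulation.

## The problem

Trials of interventions that lower ten-year cardiovascular disease (CVD)
risk — blood-pressure control, weight management, telehealth-supported
behaviour change — usually stop after about a year, but the health and
cost consequences of a lower risk score play out over decades as avoided
heart attacks, strokes and angina. `cvdcea` is for health economists and
trialists who need to turn trial-level inputs (per-arm ten-year risk
scores at baseline and 12 months, year-0 NHS costs and QALYs) into
lifetime cost-effectiveness estimates under explicit assumptions about
how long the intervention's effect on risk persists.

## The model

An annual-cycle cohort state-transition (Markov) model over the states a
CVD risk score predicts — CVD-free; acute AMI, stable/unstable angina,
TIA, stroke; post-event states; CVD and non-CVD death — expanded over a
lifetime event count capped at three. Per cycle and stratum (arm × sex):

- ten-year risk *R₁₀(t)* extrapolated over age and converted to an annual
  any-event probability *p = 1 − (1 − R₁₀)^{1/10}*, then split into
  event-specific probabilities by age/sex incidence shares;
- competing risks ordered as non-CVD death first (life table × non-CVD
  SMR), then CVD events conditional on survival, each with a
  case-fatality share flowing directly to CVD death;
- costs and utilities (age/sex EQ-5D norm × state multiplier) accrued
  with a trapezoidal half-cycle correction and discounted at 3.5%/year;
  cycle 0 is replaced by the trial-observed year-0 outcomes;
- duration-of-effect scenarios of 1, 2, 5 years or lifetime, with the
  post-effect year smoothed as the mean of the two arms' risk paths.

Probabilistic sensitivity analysis (1000 iterations; gamma costs, normal
utilities and SMR, common random numbers across arms) feeds the decision
metrics: incremental costs and QALYs, ICER = ΔC/ΔQ of the means, net
monetary benefit λΔQ − ΔC, cost-effectiveness acceptability curves
(CEACs) and cost-effectiveness-plane quadrants. An individual-level
microsimulation over the same transition tables validates the cohort
engine. A synthetic input generator provides a complete, internally
consistent stand-in parameter set (tagged `synthetic-default`) so the
whole pipeline runs with no external data; transcribed real tables can
replace any file via `load_parameter_set()`.

See `vignettes/cohort-model-methods.Rmd` for the full model description,
assumptions and validation strategy.

## Worked example

```r
library(cvdcea)

strata <- generate_cohort_strata()   # arm x sex grid, trial-level inputs
params <- generate_parameter_set()   # synthetic-default parameter tables

psa <- run_psa(strata, params, n_iter = 1000, seed = 1)
summarize_psa(psa)
```

```
Per-patient lifetime cost-effectiveness (1000 PSA iterations)

                                        1y                     ...  lifetime
Control arm NHS costs                   GBP 6,168                   GBP 6,168
Intervention arm NHS costs              GBP 6,301                   GBP 6,252
Control arm QALYs                       9.178                       9.178
Intervention arm QALYs                  9.192                       9.204
Incremental costs (95% CI)              GBP 132 (95 to 172)         GBP 83 (45 to 122)
Incremental QALYs (95% CI)              0.013 (0.004 to 0.023)      0.026 (0.016 to 0.035)
ICER                                    GBP 9,802                   GBP 3,240
Probability cost-effective at GBP 20000 0.93                        1.00
NMB at GBP 20000 (95% CI)               GBP 138 (-53 to 324)        GBP 431 (241 to 622)
Probability cost-effective at GBP 30000 0.97                        1.00
NMB at GBP 30000 (95% CI)               GBP 273 (-7 to 554)         GBP 688 (407 to 970)
```

(The 2y and 5y columns, elided here, sit between the two shown.) Reading
the output: the intervention costs about £132 more per patient over a
lifetime if its effect lasts one year — mostly the year-0 cost increment —
falling to £83 under a permanent effect as avoided events offset the
up-front cost, while the QALY gain roughly doubles from 0.013 to 0.026.
The ICER falls with duration of effect, and the probability of
cost-effectiveness at the conventional £20,000/QALY threshold rises
monotonically; plot the CEAC family with `autoplot(psa)` and the plane
with `autoplot(psa, type = "plane")`. Because the synthetic defaults
stand in for unpublished supplementary tables, absolute cost and QALY
levels are placeholders; the increments and their ordering across
durations are the meaningful structure.

Per-iteration draws are available via `tidy(psa)` or `psa_increments(psa)`,
and a file-based run (CSV inputs in, `summary.csv`/`ceac.csv`/`plane.csv`
out) via `write_synthetic_inputs()` and `run_pipeline()`.

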