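Package: cvdcea
Title: Lifetime Cost-Effectiveness of Cardiovascular Risk Interventions by
    Cohort State-Transition Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the lifetime cost-effectiveness of
    interventions that lower ten-year cardiovascular disease (CVD) risk,
    using an annual-cycle cohort state-transition (Markov) model. Ten-year
    risk scores are extrapolated over age, converted to annual event
    probabilities, split into specific acute events (myocardial infarction,
    angina, transient ischaemic attack, stroke) and propagated through an
    event-count-limited state space with competing non-CVD mortality.
    Probabilistic sensitivity analysis with gamma-distributed costs and
    normally distributed utilities yields incremental costs and QALYs,
    ICERs, net monetary benefit, cost-effectiveness acceptability curves
    and cost-effectiveness planes under alternative durations of
    intervention effect. Includes a synthetic input generator with the
    statistical structure the analysis assumes, and an individual-level
    microsimulation used to validate the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
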