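# Shared fixtures, built in code at test time.

default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(
        strata = generate_cohort_strata(),
        params = generate_parameter_set(),
        reg = default_registry()
      )
    }
    cache
  }
})

# Parameter set with every sampled quantity fixed at its mean.
zero_se_params <- function(params = generate_parameter_set()) {
  params$state_costs$se_gbp <- 0
  params$state_utilities$multiplier_se <- 0
  params$smr_se <- 0
  params
}

# A "no intervention" trial: identical risk paths and year-0 inputs.
null_strata <- function() {
  generate_cohort_strata(
    baseline_r10 = c(
      control_male = 0.3159, control_female = 0.2773,
      intervention_male = 0.3159, intervention_female = 0.2773
    ),
    followup_r10 = c(
      control_male = 0.3200, control_female = 0.2824,
      intervention_male = 0.3200, intervention_female = 0.2824
    ),
    delta_cost = 0, delta_qaly = 0,
    delta_cost_se = 0, delta_qaly_se = 0
  )
}

# Minimal alive/dead world: one living state, constant death probability.
# Exercises run_trace/accumulate/run_microsim on a closed-form case.
toy_alive_dead <- function(p_death = 0.5, horizon = 60) {
  states <- tibble::tribble(
    ~name, ~category, ~linked_acute, ~fatal,
    "event_free", "event_free", NA_character_, FALSE,
    "cvd_death", "dead", NA_character_, TRUE,
    "noncvd_death", "dead", NA_character_, TRUE
  )
  transitions <- tibble::tibble(
    from = c("event_free", "event_free"),
    to = c("cvd_death", "noncvd_death")
  )
  reg <- state_registry(states, transitions)
  space <- expanded_state_space(reg)
  labels <- space$nodes$label
  M <- matrix(0, 3, 3, dimnames = list(labels, labels))
  M["event_free", "event_free"] <- 1 - p_death
  M["event_free", "noncvd_death"] <- p_death
  M["cvd_death", "cvd_death"] <- 1
  M["noncvd_death", "noncvd_death"] <- 1
  tables <- rep(list(M), horizon)
  utilities <- setNames(c(1, 0, 0), labels)
  costs <- setNames(c(0, 0, 0), labels)
  list(
    reg = reg, space = space, tables = tables,
    utilities = utilities, costs = costs, labels = labels
  )
}

# Construct a cea_psa object directly from an increments tibble, for
# testing the decision metrics against analytically known inputs.
fake_psa <- function(delta_cost, delta_qaly, scenario = "1y",
                     base_cost = 6000, base_qaly = 8.5) {
  n <- length(delta_cost)
  iterations <- dplyr::bind_rows(
    tibble::tibble(
      iteration = seq_len(n), scenario = scenario, arm = "control",
      cost = base_cost, qaly = base_qaly
    ),
    tibble::tibble(
      iteration = seq_len(n), scenario = scenario, arm = "intervention",
      cost = base_cost + delta_cost, qaly = base_qaly + delta_qaly
    )
  )
  structure(
    list(
      iterations = iterations, n_iter = n, seed = 0L,
      scenarios = unique(scenario), strata = NULL
    ),
    class = "cea_psa"
  )
}
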