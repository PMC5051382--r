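# Probabilistic sensitivity analysis.
#
# Under the default PSA design only costs (gamma), utility multipliers
# (normal), the non-CVD SMR (normal) and the year-0 trial increments
# (normal) are sampled; incidence shares, secondary transitions and case
# fatality are fixed. The CVD core of every cycle's transition matrix is
# therefore draw-independent and is precompiled once; each iteration mixes
# it with the sampled mortality scalar and accumulates costs/QALYs through
# per-state discounted occupancy weights, which are linear in the draws.

# ---- model compilation -----------------------------------------------------

compile_model <- function(strata, params, reg = default_registry(),
                          scenarios = SCENARIO_LABELS) {
  space <- expanded_state_space(reg)
  meta <- space_meta(space)
  node_state <- space$nodes$state

  lk <- list(
    male = param_lookups(params, "male", meta$acute_states, meta$secondary_from),
    female = param_lookups(params, "female", meta$acute_states, meta$secondary_from)
  )

  traj <- risk_trajectories(strata, params, scenarios = scenarios)

  build_combo <- function(arm, sex, age0, scenario) {
    horizon <- 100 - age0
    ages <- age0 + 0:(horizon - 1)
    tr <- traj |>
      dplyr::filter(
        .data$arm == !!arm, .data$sex == !!sex, .data$age0 == !!age0,
        .data$scenario == !!scenario, .data$year < horizon
      ) |>
      dplyr::arrange(.data$year)
    C_stack <- array(0, dim = c(meta$S, meta$S, horizon))
    for (t in seq_len(horizon)) {
      band <- age_band(ages[t])
      pp <- setNames(
        tr$p_annual[t] * lk[[sex]]$shares[meta$acute_states, band],
        meta$acute_states
      )
      C_stack[, , t] <- cvd_core_matrix(meta, band, pp, lk[[sex]])
    }
    list(
      arm = arm, sex = sex, age0 = age0, scenario = scenario,
      T = horizon,
      C = C_stack,
      qx = noncvd_death_prob(ages, sex, params, smr = 1), # scaled by draw later
      norms = norm_lookup(params, sex, ages)
    )
  }

  # Control dynamics do not depend on the scenario; intervention does.
  combos <- list()
  key_of <- function(arm, sex, age0, scenario) {
    if (arm == "control") {
      paste("control", sex, age0, sep = "|")
    } else {
      paste("intervention", sex, age0, scenario, sep = "|")
    }
  }
  for (i in seq_len(nrow(strata))) {
    row <- strata[i, ]
    for (sc in scenarios) {
      k <- key_of(row$arm, row$sex, row$age0, sc)
      if (is.null(combos[[k]])) {
        combos[[k]] <- build_combo(
          row$arm, row$sex, row$age0,
          if (row$arm == "control") scenarios[1] else sc
        )
      }
    }
  }

  list(
    space = space, meta = meta, node_state = node_state,
    strata = strata, scenarios = scenarios, combos = combos,
    key_of = key_of, discount_rate = params$discount_rate
  )
}

# Discounted half-cycle occupancy weight vectors for one combo at one SMR
# draw. W: cost weights; U: QALY weights (include the per-cycle norm).
# Cycle 0 is excluded (year-0 trial override). Initial mass 1 => per person.
trace_weights <- function(combo, smr, rate, meta) {
  Tn <- combo$T
  S <- meta$S
  alive <- meta$alive
  nd <- meta$nd
  qx <- pmin(1, combo$qx * smr)
  disc <- discount_factors(rate, 0:(Tn - 1))
  occ <- numeric(S)
  occ[meta$ef] <- 1
  W <- numeric(S)
  U <- numeric(S)
  for (t in seq_len(Tn)) {
    v <- occ
    alive_mass <- sum(v[alive])
    v[alive] <- v[alive] * (1 - qx[t])
    nxt <- drop(crossprod(combo$C[, , t], v))
    nxt[nd] <- nxt[nd] + qx[t] * alive_mass
    if (t > 1L) {
      eff <- (occ + nxt) / 2
      W <- W + disc[t] * eff
      U <- U + disc[t] * combo$norms[t] * eff
    }
    occ <- nxt
  }
  list(W = W, U = U, final = occ)
}

# Full occupancy trace for a compiled combo at one SMR draw (audit /
# validation path; the PSA itself only needs the weight vectors).
trace_from_combo <- function(combo, smr, meta) {
  Tn <- combo$T
  qx <- pmin(1, combo$qx * smr)
  occ <- matrix(0, Tn + 1L, meta$S, dimnames = list(NULL, meta$labels))
  occ[1L, meta$ef] <- 1
  for (t in seq_len(Tn)) {
    v <- occ[t, ]
    alive_mass <- sum(v[meta$alive])
    v[meta$alive] <- v[meta$alive] * (1 - qx[t])
    nxt <- drop(crossprod(combo$C[, , t], v))
    nxt[meta$nd] <- nxt[meta$nd] + qx[t] * alive_mass
    occ[t + 1L, ] <- nxt
  }
  structure(occ, class = c("cohort_trace", class(occ)))
}

# ---- parameter draws -------------------------------------------------------

# Gamma draws moment-matched to (mean, se); se = 0 collapses to the mean.
rgamma_ms <- function(n, mean, se) {
  if (se <= 0 || mean <= 0) {
    return(rep(mean, n))
  }
  shape <- (mean / se)^2
  rgamma(n, shape = shape, rate = shape / mean)
}

rnorm_ms <- function(n, mean, se) {
  if (se <= 0) {
    return(rep(mean, n))
  }
  rnorm(n, mean, se)
}

#' Draw realized parameter values for the PSA
#'
#' Health-state costs are drawn from gamma distributions moment-matched to
#' their mean and standard error (`shape = (mean/se)^2`,
#' `scale = se^2/mean`); utility multipliers and the non-CVD SMR from
#' univariate normals. Utility draws are clamped to \[0, 1\] and post-event
#' draws are raised to at least their acute event's draw, so a post-event
#' state is never valued below the event itself; second and third events
#' reuse the first event's utilities by construction (values are per
#' state). Any parameter with `se = 0` is treated as fixed at its mean and
#' consumes no random numbers, so a fully degenerate parameter set
#' reproduces the deterministic model exactly.
#'
#' @param params A `cea_parameters` object.
#' @param n Number of draws.
#' @param seed Optional integer seed (set before drawing when given).
#' @return A list with matrices `cost` and `mult` (`n` rows, one column
#'   per state) and vectors `smr`, `year0_cost_z`, `year0_qaly_z` (the
#'   standard-normal deviates applied to the year-0 increment SEs).
#' @export
draw_parameters <- function(params, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sc <- params$state_costs
  su <- params$state_utilities
  cost <- matrix(0, n, nrow(sc), dimnames = list(NULL, sc$state))
  for (i in seq_len(nrow(sc))) {
    cost[, i] <- rgamma_ms(n, sc$mean_gbp[i], sc$se_gbp[i])
  }
  mult <- matrix(0, n, nrow(su), dimnames = list(NULL, su$state))
  for (i in seq_len(nrow(su))) {
    mult[, i] <- pmin(1, pmax(0, rnorm_ms(n, su$multiplier_mean[i], su$multiplier_se[i])))
  }
  # Post-event utility never below the acute event's draw.
  for (pair in list(
    c("post_ami", "ami"), c("post_tia", "tia"), c("post_stroke", "stroke")
  )) {
    if (all(pair %in% colnames(mult))) {
      mult[, pair[1]] <- pmax(mult[, pair[1]], mult[, pair[2]])
    }
  }
  smr <- pmax(1e-8, rnorm_ms(n, params$smr_mean, params$smr_se))
  list(
    cost = cost,
    mult = mult,
    smr = smr,
    year0_cost_z = rnorm(n),
    year0_qaly_z = rnorm(n)
  )
}

# ---- PSA driver ------------------------------------------------------------

# One full two-arm, all-scenario model evaluation under one joint draw.
# Returns a tibble (scenario, arm, cost, qaly) of weighted per-patient
# values.
run_model_iteration <- function(compiled, cost_draw, mult_draw, smr,
                                y0_cost_z = 0, y0_qaly_z = 0) {
  meta <- compiled$meta
  node_cost <- unname(cost_draw[compiled$node_state])
  node_mult <- unname(mult_draw[compiled$node_state])
  rate <- compiled$discount_rate

  weights_cache <- new.env(parent = emptyenv())
  get_weights <- function(key) {
    w <- weights_cache[[key]]
    if (is.null(w)) {
      w <- trace_weights(compiled$combos[[key]], smr, rate, meta)
      weights_cache[[key]] <- w
    }
    w
  }

  strata <- compiled$strata
  rows <- list()
  for (sc in compiled$scenarios) {
    for (arm in c("control", "intervention")) {
      sub <- strata[strata$arm == arm, , drop = FALSE]
      cost_pp <- 0
      qaly_pp <- 0
      for (i in seq_len(nrow(sub))) {
        r <- sub[i, ]
        w <- get_weights(compiled$key_of(arm, r$sex, r$age0, sc))
        y0c <- r$year0_cost + r$year0_cost_se * y0_cost_z
        y0q <- r$year0_qaly + r$year0_qaly_se * y0_qaly_z
        cost_pp <- cost_pp + r$weight * (y0c + sum(node_cost * w$W))
        qaly_pp <- qaly_pp + r$weight * (y0q + sum(node_mult * w$U))
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scenario = sc, arm = arm, cost = cost_pp, qaly = qaly_pp
      )
    }
  }
  purrr::list_rbind(rows)
}

#' Run the probabilistic sensitivity analysis
#'
#' Runs the full two-arm lifetime model once per iteration under a joint
#' parameter draw shared by both arms and all scenarios (common random
#' numbers isolate the intervention signal), and stores the per-arm
#' weighted per-patient discounted costs and QALYs. Fully reproducible
#' from `seed`.
#'
#' @param strata Cohort strata ([generate_cohort_strata()]).
#' @param params A `cea_parameters` object.
#' @param reg A [state_registry()].
#' @param scenarios Duration-of-effect labels to run.
#' @param n_iter Number of PSA iterations (>= 1).
#' @param seed Integer seed controlling every draw.
#' @return A `cea_psa` object: list with `iterations` (tibble: iteration,
#'   scenario, arm, cost, qaly), `n_iter`, `seed`, `scenarios`, `strata`.
#' @export
#' @examples
#' \donttest{
#' strata <- generate_cohort_strata()
#' params <- generate_parameter_set()
#' psa <- run_psa(strata, params, n_iter = 20, seed = 1)
#' summarize_psa(psa)
#' }
run_psa <- function(strata, params, reg = default_registry(),
                    scenarios = SCENARIO_LABELS, n_iter = 1000,
                    seed = 1L) {
  if (n_iter < 1) abort("n_iter must be at least 1")
  compiled <- compile_model(strata, params, reg, scenarios)
  draws <- draw_parameters(params, n = n_iter, seed = seed)
  its <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    its[[i]] <- run_model_iteration(
      compiled,
      draws$cost[i, ], draws$mult[i, ], draws$smr[i],
      draws$year0_cost_z[i], draws$year0_qaly_z[i]
    ) |>
      dplyr::mutate(iteration = i, .before = 1)
  }
  structure(
    list(
      iterations = purrr::list_rbind(its),
      n_iter = as.integer(n_iter),
      seed = as.integer(seed),
      scenarios = scenarios,
      strata = strata
    ),
    class = "cea_psa"
  )
}

#' Deterministic (mean-parameter) model run
#'
#' Evaluates the model once with every parameter fixed at its mean — the
#' limit of the PSA as all standard errors go to zero.
#'
#' @inheritParams run_psa
#' @return A tibble (`scenario`, `arm`, `cost`, `qaly`).
#' @export
run_deterministic <- function(strata, params, reg = default_registry(),
                              scenarios = SCENARIO_LABELS) {
  compiled <- compile_model(strata, params, reg, scenarios)
  run_model_iteration(
    compiled,
    setNames(params$state_costs$mean_gbp, params$state_costs$state),
    setNames(
      params$state_utilities$multiplier_mean,
      params$state_utilities$state
    ),
    params$smr_mean
  )
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(
    "<cea_psa> ", x$n_iter, " iterations x ",
    length(x$scenarios), " scenarios (seed ", x$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname run_psa
#' @param x A `cea_psa` object.
#' @param ... Unused.
#' @method tidy cea_psa
#' @export
tidy.cea_psa <- function(x, ...) x$iterations

#' @rdname run_psa
#' @method glance cea_psa
#' @export
glance.cea_psa <- function(x, ...) {
  tibble::tibble(
    n_iter = x$n_iter,
    n_scenarios = length(x$scenarios),
    seed = x$seed
  )
}

#' Per-iteration incremental costs and QALYs
#'
#' @param psa A `cea_psa` object.
#' @return A tibble (`iteration`, `scenario`, `delta_cost`, `delta_qaly`)
#'   of intervention-minus-control differences.
#' @export
psa_increments <- function(psa) {
  psa$iterations |>
    tidyr::pivot_wider(
      names_from = "arm", values_from = c("cost", "qaly")
    ) |>
    dplyr::mutate(
      delta_cost = .data$cost_intervention - .data$cost_control,
      delta_qaly = .data$qaly_intervention - .data$qaly_control
    ) |>
    dplyr::select("iteration", "scenario", "delta_cost", "delta_qaly")
}
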