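# Cohort engine: deterministic trace for one stratum under one realized
# parameter draw; trapezoidal half-cycle correction; discounting; year-0
# trial override.

#' Run a cohort trace
#'
#' Propagates an initial occupancy vector through a sequence of per-cycle
#' transition matrices. Probability mass is conserved at every cycle.
#'
#' @param initial Named numeric occupancy vector over the expanded states
#'   (mass 1 for per-patient results, or a cohort of e.g. 1000 persons).
#' @param tables List of row-stochastic transition matrices (cycles
#'   `0..T-1`), e.g. from [model_tables()].
#' @return A `(T+1) x S` occupancy matrix of class `cohort_trace`; row
#'   `t+1` is the occupancy at the start of cycle `t`.
#' @export
run_trace <- function(initial, tables) {
  if (length(tables) == 0L) abort("at least one transition table is required")
  S <- length(initial)
  for (t in seq_along(tables)) {
    M <- tables[[t]]
    if (!is.matrix(M) || nrow(M) != S || ncol(M) != S) {
      abort(paste0("table ", t, " does not match the state space"))
    }
    if (any(abs(rowSums(M) - 1) > 1e-8) || any(M < 0)) {
      abort(paste0("table ", t, " is not row-stochastic"))
    }
  }
  occ <- matrix(0, length(tables) + 1L, S,
    dimnames = list(NULL, names(initial))
  )
  occ[1L, ] <- initial
  for (t in seq_along(tables)) {
    occ[t + 1L, ] <- drop(crossprod(tables[[t]], occ[t, ]))
  }
  structure(occ, class = c("cohort_trace", class(occ)))
}

#' Tidy a cohort trace
#'
#' @param x A `cohort_trace` matrix.
#' @param ... Unused.
#' @return A long tibble (`cycle`, `state`, `occupancy`).
#' @method tidy cohort_trace
#' @export
tidy.cohort_trace <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    cycle = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
    state = rep(colnames(m), each = nrow(m)),
    occupancy = as.vector(m)
  ) |>
    dplyr::arrange(.data$cycle, match(.data$state, colnames(m)))
}

#' Accumulate lifetime costs and QALYs from a cohort trace
#'
#' Applies the half-cycle correction by trapezoidal occupancy averaging —
#' cycle `t` accrues on `(occupancy[t] + occupancy[t+1]) / 2` — then costs
#' each cycle with the per-state cost vector and values it with per-state
#' utility multipliers times the cycle's population utility norm, and
#' discounts at `(1 + rate)^-t`. Cycle 0 is optionally overridden by
#' trial-observed year-0 cost/QALY totals (undiscounted); simulated
#' dynamics then start contributing at cycle 1.
#'
#' @param trace A [run_trace()] result (occupancy `(T+1) x S`).
#' @param state_costs Named per-state annual costs (GBP/cycle).
#' @param state_utilities Named per-state utility multipliers in \[0, 1\].
#' @param discount_rate Annual discount rate (>= 0).
#' @param norms Population utility norm per cycle (scalar or length-`T`
#'   vector; multiplies the state multipliers).
#' @param year0 Optional list with per-person `cost` and `qaly` that
#'   replace the simulated cycle-0 accruals.
#' @return An `arm_result`: list with `per_cycle` (tibble: cycle, cost,
#'   qaly, discount_factor, disc_cost, disc_qaly), `totals` (discounted and
#'   undiscounted totals) and `per_person` (totals divided by the initial
#'   mass).
#' @export
accumulate <- function(trace, state_costs, state_utilities,
                       discount_rate = 0.035, norms = 1, year0 = NULL) {
  m <- unclass(trace)
  Tn <- nrow(m) - 1L
  sts <- colnames(m)
  if (is.null(sts)) abort("trace must have state column names")
  c_vec <- state_costs[sts]
  u_vec <- state_utilities[sts]
  if (anyNA(c_vec)) abort("state_costs missing for some trace states")
  if (anyNA(u_vec)) abort("state_utilities missing for some trace states")
  if (any(c_vec < 0)) abort("negative state cost")
  if (any(u_vec < 0 | u_vec > 1)) abort("state utilities must lie in [0, 1]")
  norm_vec <- rep_len(norms, Tn)
  if (any(norm_vec < 0 | norm_vec > 1)) abort("norms must lie in [0, 1]")

  eff <- (m[-(Tn + 1L), , drop = FALSE] + m[-1L, , drop = FALSE]) / 2
  cost_cyc <- as.vector(eff %*% c_vec)
  qaly_cyc <- as.vector(eff %*% u_vec) * norm_vec
  mass <- sum(m[1L, ])
  if (!is.null(year0)) {
    cost_cyc[1L] <- year0$cost * mass
    qaly_cyc[1L] <- year0$qaly * mass
  }
  disc <- discount_factors(discount_rate, 0:(Tn - 1L))
  per_cycle <- tibble::tibble(
    cycle = 0:(Tn - 1L),
    cost = cost_cyc,
    qaly = qaly_cyc,
    discount_factor = disc,
    disc_cost = cost_cyc * disc,
    disc_qaly = qaly_cyc * disc
  )
  totals <- list(
    cost = sum(per_cycle$disc_cost),
    qaly = sum(per_cycle$disc_qaly),
    undisc_cost = sum(per_cycle$cost),
    undisc_qaly = sum(per_cycle$qaly)
  )
  structure(
    list(
      per_cycle = per_cycle,
      totals = totals,
      per_person = lapply(totals, function(x) x / mass),
      mass = mass
    ),
    class = "arm_result"
  )
}

#' @export
print.arm_result <- function(x, ...) {
  cat("<arm_result> per-person discounted cost GBP ",
    format(round(x$per_person$cost, 2), big.mark = ","),
    ", QALYs ", round(x$per_person$qaly, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname accumulate
#' @param x An `arm_result`.
#' @param ... Unused.
#' @method tidy arm_result
#' @export
tidy.arm_result <- function(x, ...) x$per_cycle

#' @rdname accumulate
#' @method glance arm_result
#' @export
glance.arm_result <- function(x, ...) {
  tibble::tibble(
    cost = x$per_person$cost,
    qaly = x$per_person$qaly,
    undisc_cost = x$per_person$undisc_cost,
    undisc_qaly = x$per_person$undisc_qaly
  )
}

#' Deterministic single-arm lifetime run
#'
#' Convenience audit path: builds the per-cycle tables at the given SMR,
#' runs the trace from a CVD-free cohort and accumulates per-person
#' discounted costs and QALYs with the year-0 trial override.
#'
#' @inheritParams model_tables
#' @param cohort_size Cohort size used for the trace occupancy (results
#'   are reported per person regardless).
#' @return A list: `result` (an `arm_result`), `trace`, `tables` (the
#'   [model_tables()] output).
#' @export
run_arm <- function(strata, params, arm, sex, scenario,
                    smr = NULL, reg = default_registry(),
                    cohort_size = 1000) {
  smr <- smr %||% params$smr_mean
  mt <- model_tables(strata, params, arm, sex, scenario, smr = smr, reg = reg)
  meta <- space_meta(mt$space)
  initial <- setNames(numeric(meta$S), meta$labels)
  initial[meta$ef] <- cohort_size
  trace <- run_trace(initial, mt$tables)
  node_cost <- node_values(mt$space, params$state_costs, "mean_gbp")
  node_util <- node_values(mt$space, params$state_utilities, "multiplier_mean")
  res <- accumulate(
    trace, node_cost, node_util,
    discount_rate = params$discount_rate,
    norms = mt$norms,
    year0 = list(
      cost = mt$stratum$year0_cost,
      qaly = mt$stratum$year0_qaly
    )
  )
  list(result = res, trace = trace, tables = mt)
}

# Map state-level values onto expanded nodes (named by node label).
node_values <- function(space, table, col) {
  idx <- match(space$nodes$state, table$state)
  if (anyNA(idx)) {
    abort(paste0(
      "no value for state(s): ",
      paste(unique(space$nodes$state[is.na(idx)]), collapse = ", ")
    ))
  }
  setNames(table[[col]][idx], space$nodes$label)
}
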