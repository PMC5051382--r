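# Individual-level microsimulation over the same expanded state space and
# per-cycle transition tables as the cohort engine. Used to validate the
# cohort trace: both estimators share the estimand exactly (same
# trapezoidal half-cycle weights, discounting and year-0 override), so the
# cohort value must lie within Monte-Carlo error of the microsimulation
# mean.

#' Run the individual-level microsimulation
#'
#' Each of `n` individuals starts CVD-free and walks the per-cycle
#' transition tables by categorical sampling. Costs and QALYs accrue with
#' the cohort engine's conventions: cycle `t` contributes the average of
#' the state values at its start and end (trapezoidal half-cycle
#' correction), discounted at `(1 + rate)^-t`, with cycle 0 replaced by
#' the year-0 trial override when given.
#'
#' @param tables List of per-cycle transition matrices (e.g.
#'   [model_tables()]`$tables`).
#' @param space The expanded state space the tables are defined over.
#' @param state_costs,state_utilities State-level cost / utility tables
#'   (as in a `cea_parameters` object) or named per-node vectors.
#' @param norms Utility norm per cycle (scalar or length-`T` vector).
#' @param discount_rate Annual discount rate.
#' @param year0 Optional list with per-person `cost` and `qaly` replacing
#'   cycle-0 accruals.
#' @param n Number of simulated individuals (> 0).
#' @param seed Integer seed.
#' @return A `microsim_result`: list with `n`, `mean_cost`, `se_cost`,
#'   `mean_qaly`, `se_qaly` and `event_counts` (tibble of lifetime CVD
#'   event counts).
#' @export
run_microsim <- function(tables, space, state_costs, state_utilities,
                         norms = 1, discount_rate = 0.035, year0 = NULL,
                         n = 10000, seed = 1L) {
  if (n <= 0) abort("n must be positive")
  meta <- space_meta(space)
  S <- meta$S
  cvec <- if (is.data.frame(state_costs)) {
    node_values(space, state_costs, "mean_gbp")
  } else {
    state_costs[meta$labels]
  }
  uvec <- if (is.data.frame(state_utilities)) {
    node_values(space, state_utilities, "multiplier_mean")
  } else {
    state_utilities[meta$labels]
  }
  if (anyNA(cvec) || anyNA(uvec)) {
    abort("costs/utilities must cover every expanded state")
  }
  Tn <- length(tables)
  norm_vec <- rep_len(norms, Tn)
  node_count <- space$nodes$count
  is_dead <- space$nodes$category == "dead"

  set.seed(seed)
  cur <- rep.int(meta$ef, n)
  cost <- numeric(n)
  qaly <- numeric(n)
  evc <- integer(n)
  for (t in seq_len(Tn)) {
    M <- tables[[t]]
    nxt <- integer(n)
    for (s in unique(cur)) {
      idx <- which(cur == s)
      if (is_dead[s]) {
        nxt[idx] <- s # absorbing; skip sampling
      } else {
        nxt[idx] <- sample.int(S, length(idx), replace = TRUE, prob = M[s, ])
      }
    }
    tc <- t - 1L
    disc <- discount_factors(discount_rate, tc)
    if (tc == 0L && !is.null(year0)) {
      cost <- cost + year0$cost
      qaly <- qaly + year0$qaly
    } else {
      cost <- cost + disc * (cvec[cur] + cvec[nxt]) / 2
      qaly <- qaly + disc * norm_vec[t] * (uvec[cur] + uvec[nxt]) / 2
    }
    evc <- pmax(evc, ifelse(is_dead[nxt], 0L, node_count[nxt]))
    cur <- nxt
  }
  structure(
    list(
      n = as.integer(n),
      mean_cost = mean(cost),
      se_cost = sd(cost) / sqrt(n),
      mean_qaly = mean(qaly),
      se_qaly = sd(qaly) / sqrt(n),
      event_counts = tibble::tibble(events = evc) |>
        dplyr::count(.data$events, name = "individuals")
    ),
    class = "microsim_result"
  )
}

#' @export
print.microsim_result <- function(x, ...) {
  cat("<microsim_result> n = ", x$n,
    "; cost ", round(x$mean_cost, 2), " (se ", signif(x$se_cost, 3),
    "); QALYs ", round(x$mean_qaly, 4), " (se ", signif(x$se_qaly, 4), ")\n",
    sep = ""
  )
  invisible(x)
}
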