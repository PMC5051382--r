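# Per-cycle transition tables over the expanded state space.
#
# Competing-risk ordering: non-CVD death is applied first; CVD dynamics
# act on the surviving fraction; residual mass stays in the current (or
# post-event) state. Each fatal share of an event routes directly to CVD
# death at the event cycle. This keeps every row stochastic without ad hoc
# rescaling.

#' Annual probability of non-CVD death
#'
#' Life-table all-cause probability at the attained age and sex, scaled by
#' the non-CVD standardised mortality ratio and capped at 1.
#'
#' @param age Attained age (integer years; exact life-table lookup).
#' @param sex `"male"` or `"female"`.
#' @param params A `cea_parameters` object.
#' @param smr Standardised mortality ratio draw (> 0).
#' @return Probability of death from causes unrelated to CVD within one
#'   annual cycle.
#' @export
noncvd_death_prob <- function(age, sex, params, smr = 1) {
  lt <- params$life_table
  idx <- match(
    paste(sex, age),
    paste(lt$sex, lt$age)
  )
  if (anyNA(idx)) {
    abort(paste0(
      "life table has no row for ",
      paste(sex[is.na(idx)][1], age[is.na(idx)][1])
    ))
  }
  if (any(smr <= 0)) abort("smr must be positive")
  pmin(1, lt$qx[idx] * smr)
}

# Fast per-sex lookup structures used when assembling many tables.
# Returns matrices keyed by [event/state, band] for the given sex.
param_lookups <- function(params, sex, events, from_states) {
  bands <- AGE_BANDS
  pick <- function(df, rows, row_col, val_col) {
    m <- matrix(NA_real_, length(rows), length(bands),
      dimnames = list(rows, bands)
    )
    sub <- df[df$sex == sex, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      r <- sub[[row_col]][i]
      if (r %in% rows) m[r, sub$age_band[i]] <- sub[[val_col]][i]
    }
    m
  }
  shares <- pick(params$incidence, events, "event", "share")
  cf <- pick(params$case_fatality, events, "event", "prob")
  sec <- array(0, dim = c(length(from_states), length(events), length(bands)),
    dimnames = list(from_states, events, bands)
  )
  sub <- params$secondary[params$secondary$sex == sex, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    f <- sub$from_state[i]
    t <- sub$to_state[i]
    if (f %in% from_states && t %in% events) {
      sec[f, t, sub$age_band[i]] <- sub$prob[i]
    }
  }
  if (anyNA(shares)) abort(paste0("incidence table incomplete for sex ", sex))
  if (anyNA(cf)) abort(paste0("case-fatality table incomplete for sex ", sex))
  list(shares = shares, case_fatality = cf, secondary = sec)
}

# Node-level metadata reused by the core-matrix builder.
space_meta <- function(space) {
  nodes <- space$nodes
  reg <- space$registry
  S <- nrow(nodes)
  labels <- nodes$label
  idx <- setNames(seq_len(S), labels)
  acute_states <- unique(nodes$state[nodes$category == "acute"])
  post_of <- post_state_map(reg$states)
  node_of <- function(state, count) {
    lab <- if (state %in% c(reg$cvd_death, reg$noncvd_death)) {
      state
    } else if (nodes$category[match(state, nodes$state)] == "event_free") {
      state
    } else {
      paste0(state, ".", count)
    }
    i <- idx[lab]
    if (is.na(i)) abort(paste0("expanded node not found: ", lab))
    unname(i)
  }
  list(
    S = S, labels = labels, idx = idx, nodes = nodes,
    ef = unname(idx[nodes$label[nodes$category == "event_free"][1]]),
    cd = unname(idx[reg$cvd_death]),
    nd = unname(idx[reg$noncvd_death]),
    dead = unname(idx[nodes$label[nodes$category == "dead"]]),
    alive = unname(idx[nodes$label[nodes$category != "dead"]]),
    acute_states = acute_states,
    post_of = post_of,
    max_events = reg$max_events,
    node_of = node_of,
    # Originating states with secondary-event exposure: post states and
    # chronic acute states (angina).
    secondary_from = unique(nodes$state[nodes$category == "post" | nodes$chronic])
  )
}

# CVD dynamics conditional on surviving non-CVD mortality in the cycle:
# a row-stochastic matrix over the expanded nodes.
cvd_core_matrix <- function(meta, band, primary_probs, lk) {
  S <- meta$S
  C <- matrix(0, S, S, dimnames = list(meta$labels, meta$labels))
  for (d in meta$dead) C[d, d] <- 1

  events <- names(primary_probs)
  cf <- lk$case_fatality[events, band]

  # Event-free row: primary events with fatal/non-fatal split.
  p <- primary_probs
  if (sum(p) > 1 + 1e-12) {
    abort(paste0(
      "primary event probabilities sum to ", signif(sum(p), 6),
      " > 1; refusing to rescale"
    ))
  }
  C[meta$ef, meta$cd] <- sum(p * cf)
  for (e in events) {
    C[meta$ef, meta$node_of(e, 1L)] <- p[e] * (1 - cf[e])
  }
  C[meta$ef, meta$ef] <- 1 - sum(p)

  nodes <- meta$nodes
  for (i in seq_len(S)) {
    st <- nodes$state[i]
    ct <- nodes$count[i]
    cat <- nodes$category[i]
    if (cat %in% c("event_free", "dead")) next
    if (cat == "acute" && !nodes$chronic[i]) {
      # Pure acute states last one cycle, then the linked post state.
      C[i, meta$node_of(meta$post_of[[st]], ct)] <- 1
    } else {
      # Post-event and chronic angina states: secondary events while the
      # lifetime cap allows, residual mass persists.
      if (ct < meta$max_events) {
        q <- lk$secondary[st, events, band]
        if (sum(q) > 1 + 1e-12) {
          abort(paste0(
            "secondary event probabilities from '", st, "' sum to ",
            signif(sum(q), 6), " > 1; refusing to rescale"
          ))
        }
        C[i, meta$cd] <- C[i, meta$cd] + sum(q * cf)
        for (e in events) {
          j <- meta$node_of(e, ct + 1L)
          C[i, j] <- C[i, j] + q[e] * (1 - cf[e])
        }
        C[i, i] <- C[i, i] + 1 - sum(q)
      } else {
        C[i, i] <- C[i, i] + 1
      }
    }
  }
  C
}

# Mix CVD dynamics with the non-CVD mortality scalar for the cycle.
mix_mortality <- function(C, qx, meta) {
  M <- C
  M[meta$alive, ] <- (1 - qx) * C[meta$alive, , drop = FALSE]
  M[meta$alive, meta$nd] <- M[meta$alive, meta$nd] + qx
  M
}

#' Build one annual-cycle transition table
#'
#' Assembles the row-stochastic transition matrix over the expanded
#' (state, event count) space for one cycle: non-CVD death first (life
#' table times SMR), then, conditional on survival, primary events from
#' the CVD-free state (with each event's case-fatality share routed to CVD
#' death), a deterministic move from acute states to their post-event
#' state, secondary events from post-event and chronic states, and
#' persistence of the residual mass. States at the lifetime event cap
#' admit only persistence and death. At attained ages of 100 or more all
#' surviving mass is sent to non-CVD death.
#'
#' @param space Expanded state space ([expanded_state_space()]).
#' @param age Attained age at the cycle.
#' @param sex `"male"` or `"female"`.
#' @param primary_probs Named per-acute-event annual probabilities from
#'   [split_events()] (applied from the CVD-free state).
#' @param params A `cea_parameters` object.
#' @param smr Standardised mortality ratio (draw or mean).
#' @return An S x S matrix with expanded-node dimnames; every row sums
#'   to 1.
#' @export
build_cycle_table <- function(space, age, sex, primary_probs, params,
                              smr = 1) {
  meta <- space_meta(space)
  events <- meta$acute_states
  if (!setequal(names(primary_probs), events)) {
    abort(paste0(
      "primary_probs must be named by the acute events: ",
      paste(events, collapse = ", ")
    ))
  }
  primary_probs <- primary_probs[events]
  lk <- param_lookups(params, sex, events, meta$secondary_from)
  band <- age_band(age)
  if (age >= 100) {
    M <- matrix(0, meta$S, meta$S, dimnames = list(meta$labels, meta$labels))
    for (d in meta$dead) M[d, d] <- 1
    M[meta$alive, meta$nd] <- 1
  } else {
    C <- cvd_core_matrix(meta, band, primary_probs, lk)
    qx <- noncvd_death_prob(age, sex, params, smr)
    M <- mix_mortality(C, qx, meta)
  }
  bad <- which(abs(rowSums(M) - 1) > 1e-8)
  if (length(bad) > 0L) {
    abort(paste0(
      "transition rows do not sum to 1: ",
      paste(meta$labels[bad], collapse = ", ")
    ))
  }
  M
}

#' Per-cycle transition tables for one stratum and scenario
#'
#' Audit-grade assembly of the full sequence of annual transition matrices
#' a stratum experiences under a duration-of-effect scenario, from entry
#' age to the forced-death horizon at age 100. This is the same dynamics
#' the cohort engine and microsimulation use.
#'
#' @param strata Cohort strata (both arms of the stratum's sex must be
#'   present, since intervention paths revert to the control path).
#' @param params A `cea_parameters` object.
#' @param arm `"control"` or `"intervention"`.
#' @param sex `"male"` or `"female"`.
#' @param scenario Duration-of-effect label.
#' @param smr Standardised mortality ratio (draw or mean).
#' @param reg A [state_registry()].
#' @return A list: `tables` (list of per-cycle matrices, cycles
#'   `0..T-1`), `space`, `ages`, `norms` (utility norm per cycle) and the
#'   stratum row.
#' @export
model_tables <- function(strata, params, arm, sex, scenario,
                         smr = 1, reg = default_registry()) {
  space <- expanded_state_space(reg)
  meta <- space_meta(space)
  stratum <- strata |>
    dplyr::filter(.data$arm == !!arm, .data$sex == !!sex)
  if (nrow(stratum) != 1L) {
    abort("model_tables() expects exactly one stratum row per arm and sex")
  }
  traj <- risk_trajectories(
    strata |> dplyr::filter(.data$sex == !!sex),
    params,
    scenarios = scenario
  ) |>
    dplyr::filter(.data$arm == !!arm)
  horizon <- 100 - stratum$age0
  lk <- param_lookups(params, sex, meta$acute_states, meta$secondary_from)
  ages <- stratum$age0 + 0:(horizon - 1)
  tables <- vector("list", horizon)
  for (t in seq_len(horizon)) {
    age_t <- ages[t]
    p_any <- traj$p_annual[traj$year == t - 1]
    pp <- setNames(
      p_any * lk$shares[meta$acute_states, age_band(age_t)],
      meta$acute_states
    )
    C <- cvd_core_matrix(meta, age_band(age_t), pp, lk)
    qx <- noncvd_death_prob(age_t, sex, params, smr)
    tables[[t]] <- mix_mortality(C, qx, meta)
  }
  norms <- norm_lookup(params, sex, ages)
  list(
    tables = tables, space = space, ages = ages, norms = norms,
    stratum = stratum
  )
}

# Utility norms at attained ages (vectorized exact band lookup).
norm_lookup <- function(params, sex, ages) {
  nm <- params$norms[params$norms$sex == sex, , drop = FALSE]
  idx <- match(norm_band(ages), nm$age_band)
  if (anyNA(idx)) {
    abort(paste0(
      "utility norms missing for sex ", sex, ", band ",
      norm_band(ages[is.na(idx)][1])
    ))
  }
  nm$utility[idx]
}
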