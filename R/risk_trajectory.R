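# Per-stratum, per-scenario annual CVD-risk paths: extrapolate ten-year
# risk over age, apply the duration-of-effect scenario with its smoothing
# rule, convert to annual probabilities and split by specific event.

#' Convert ten-year risk to an annual any-event probability
#'
#' Uses the constant-hazard complement `1 - (1 - r10)^(1/10)`, the standard
#' decision-modelling conversion; it is monotone in `r10` and inverse
#' consistent with [ten_year_risk()].
#'
#' @param r10 Ten-year risk probability (vectorized), in \[0, 1\].
#' @return Annual probability of any CVD event.
#' @export
#' @examples
#' annualize_risk(0.3159)
annualize_risk <- function(r10) {
  check_probability(r10, "r10")
  1 - (1 - r10)^(1 / 10)
}

#' @rdname annualize_risk
#' @param p_annual Annual probability to convert back to a ten-year risk.
#' @export
ten_year_risk <- function(p_annual) {
  check_probability(p_annual, "p_annual")
  1 - (1 - p_annual)^10
}

#' Extrapolate ten-year risk over the model horizon
#'
#' Year 0 is the baseline ten-year risk; year 1 the 12-month
#' baseline-adjusted risk. From year 2 the score grows multiplicatively by
#' the male age-specific growth rate at the attained age (female paths use
#' the male growth table, which keeps female risk below male risk at all
#' ages and caps growth plausibly). Beyond age 84, where the risk score is
#' not validated, the ten-year score grows by 1 percentage point per year
#' by default (`elderly_growth = "additive"`; `"relative"` applies +1%
#' multiplicatively instead). Risk is capped at 1 throughout.
#'
#' Growth rates are looked up at exact integer attained ages (no
#' interpolation); a missing in-range age is an error.
#'
#' @param baseline_r10,followup_r10 Year-0 and year-1 ten-year risks.
#' @param age0 Entry age in years.
#' @param growth Growth table: tibble with columns `age`, `growth_rate`.
#' @param horizon Number of model years (> 0).
#' @param elderly_growth Extrapolation rule beyond age 84.
#' @return Numeric vector of ten-year risks for years `0..horizon`.
#' @export
extrapolate_r10 <- function(baseline_r10, followup_r10, age0, growth,
                            horizon,
                            elderly_growth = c("additive", "relative")) {
  elderly_growth <- match.arg(elderly_growth)
  if (!is.numeric(horizon) || horizon <= 0) {
    abort("horizon must be a positive number of years")
  }
  check_probability(c(baseline_r10, followup_r10), "r10")
  g <- setNames(growth$growth_rate, as.character(growth$age))
  r <- numeric(horizon + 1)
  r[1] <- baseline_r10
  r[2] <- followup_r10
  for (t in seq_len(max(0, horizon - 1)) + 1) { # model years 2..horizon
    age_t <- age0 + t
    if (age_t < 85) {
      gt <- g[as.character(age_t)]
      if (is.na(gt)) {
        abort(paste0("growth table has no entry for age ", age_t))
      }
      r[t + 1] <- min(1, r[t] * (1 + gt))
    } else if (elderly_growth == "additive") {
      r[t + 1] <- min(1, r[t] + 0.01)
    } else {
      r[t + 1] <- min(1, r[t] * 1.01)
    }
  }
  unname(r)
}

#' Apply a duration-of-effect scenario to the intervention risk path
#'
#' For a finite duration `D`, the intervention arm keeps its own risk path
#' for model years 1..`D`; in year `D + 1` risk is the average of the
#' intervention and control paths (the smoothing rule that avoids a sudden
#' jump when the effect expires); from year `D + 2` onwards the
#' intervention arm takes the control path. A lifetime duration (`Inf`)
#' returns the intervention path unchanged. Year 0 is never modified: its
#' outcomes come from trial data, not simulated risk.
#'
#' @param intv_r10,ctrl_r10 Ten-year risk paths (years `0..T`), equal
#'   length, same stratum ages.
#' @param duration Duration of effect in model years (positive integer or
#'   `Inf`).
#' @return The intervention arm's risk path under the scenario.
#' @export
apply_effect_scenario <- function(intv_r10, ctrl_r10, duration) {
  if (length(intv_r10) != length(ctrl_r10)) {
    abort("intervention and control risk paths must have equal length")
  }
  if (is.infinite(duration)) {
    return(intv_r10)
  }
  if (!is.numeric(duration) || duration < 1 || duration != round(duration)) {
    abort("duration must be a positive integer number of years or Inf")
  }
  n <- length(intv_r10)
  out <- ctrl_r10
  out[1] <- intv_r10[1] # year 0 untouched
  keep <- seq_len(min(duration, n - 1)) + 1 # years 1..D
  out[keep] <- intv_r10[keep]
  j <- duration + 2 # year D + 1
  if (j <= n) out[j] <- (intv_r10[j] + ctrl_r10[j]) / 2
  out
}

#' Split an annual any-event probability into specific acute events
#'
#' Multiplies the annual probability by the incidence share of each acute
#' event for the given age band and sex; the event-specific probabilities
#' sum back to the input.
#'
#' @param p_annual Annual any-event probability.
#' @param age Attained age (determines the age band).
#' @param sex `"male"` or `"female"`.
#' @param params A `cea_parameters` object.
#' @return Named numeric vector of per-event annual probabilities.
#' @export
split_events <- function(p_annual, age, sex, params) {
  check_probability(p_annual, "p_annual")
  band <- age_band(age)
  row <- params$incidence |>
    dplyr::filter(.data$sex == !!sex, .data$age_band == band)
  if (nrow(row) == 0L) {
    abort(paste0("no incidence shares for sex '", sex, "', age band ", band))
  }
  setNames(p_annual * row$share, row$event)
}

#' Build per-stratum risk trajectories for every scenario
#'
#' Combines [extrapolate_r10()], [apply_effect_scenario()] and
#' [annualize_risk()] across the cohort strata. Control-arm paths do not
#' depend on the scenario but are repeated per scenario for convenience.
#' The horizon per stratum is `100 - age0` (death is forced at age 100).
#'
#' @param strata Cohort strata ([generate_cohort_strata()]).
#' @param params A `cea_parameters` object.
#' @param scenarios Character vector of duration-of-effect labels among
#'   `"1y"`, `"2y"`, `"5y"`, `"lifetime"`.
#' @param elderly_growth See [extrapolate_r10()].
#' @return A tibble with columns `scenario`, `arm`, `sex`, `age0`, `year`,
#'   `age`, `r10`, `p_annual`.
#' @export
risk_trajectories <- function(strata, params,
                              scenarios = SCENARIO_LABELS,
                              elderly_growth = "additive") {
  out <- list()
  for (sx in unique(strata$sex)) {
    for (a0 in unique(strata$age0[strata$sex == sx])) {
      ctrl <- strata |>
        dplyr::filter(.data$sex == sx, .data$age0 == a0, .data$arm == "control")
      intv <- strata |>
        dplyr::filter(
          .data$sex == sx, .data$age0 == a0,
          .data$arm == "intervention"
        )
      horizon <- 100 - a0
      ctrl_path <- extrapolate_r10(
        ctrl$baseline_r10[1], ctrl$followup_r10[1], a0, params$growth,
        horizon, elderly_growth
      )
      intv_raw <- extrapolate_r10(
        intv$baseline_r10[1], intv$followup_r10[1], a0, params$growth,
        horizon, elderly_growth
      )
      for (sc in scenarios) {
        d <- scenario_duration(sc)
        intv_path <- apply_effect_scenario(intv_raw, ctrl_path, d)
        yrs <- 0:horizon
        out <- c(out, list(
          tibble::tibble(
            scenario = sc, arm = "control", sex = sx, age0 = a0,
            year = yrs, age = a0 + yrs, r10 = ctrl_path,
            p_annual = annualize_risk(ctrl_path)
          ),
          tibble::tibble(
            scenario = sc, arm = "intervention", sex = sx, age0 = a0,
            year = yrs, age = a0 + yrs, r10 = intv_path,
            p_annual = annualize_risk(intv_path)
          )
        ))
      }
    }
  }
  purrr::list_rbind(out)
}
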