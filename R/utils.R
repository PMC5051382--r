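# Shared helpers: age banding, scenario labels, small checks.

# Broad bands used by incidence, secondary-event and case-fatality tables.
AGE_BANDS <- c("40-54", "55-64", "65-74", "75-84", "85+")

# Scenario labels for duration of intervention effect (model years).
SCENARIO_LABELS <- c("1y", "2y", "5y", "lifetime")

age_band <- function(age) {
  as.character(cut(pmax(age, 40),
    breaks = c(39, 54, 64, 74, 84, Inf),
    labels = AGE_BANDS
  ))
}

# 5-year bands used by the population utility-norm table (ages 40-99).
norm_band <- function(age) {
  lo <- pmin(pmax(floor(age / 5) * 5, 40), 95)
  paste0(lo, "-", lo + 4)
}

norm_band_levels <- function() norm_band(seq(40, 99, by = 5))

scenario_duration <- function(label) {
  d <- c(`1y` = 1, `2y` = 2, `5y` = 5, lifetime = Inf)[label]
  if (anyNA(d)) {
    abort(paste0(
      "unknown scenario label(s): ",
      paste(label[is.na(d)], collapse = ", "),
      " (must be one of ", paste(SCENARIO_LABELS, collapse = ", "), ")"
    ))
  }
  unname(d)
}

scenario_label <- function(duration) {
  ifelse(is.infinite(duration), "lifetime", paste0(duration, "y"))
}

check_probability <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(paste0(what, " must lie in [0, 1]"))
  }
  invisible(x)
}

discount_factors <- function(rate, cycles) (1 + rate)^(-cycles)
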