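# Decision metrics: ICER, net monetary benefit, acceptability curves,
# cost-effectiveness plane quadrants, and the per-scenario summary table.

#' Incremental cost-effectiveness ratio
#'
#' Computes `delta_cost / delta_qaly` where defined, and returns the
#' conventional dominance labels otherwise: `"dominant"` (cheaper and more
#' effective), `"dominated"` (costlier and less effective),
#' `"indifferent"` (no difference on either axis) and signed-infinity
#' labels when the QALY difference is exactly zero.
#'
#' @param delta_cost Incremental cost (GBP), vectorized.
#' @param delta_qaly Incremental QALYs, vectorized.
#' @return A tibble with columns `delta_cost`, `delta_qaly`, `icer`
#'   (numeric, `NA` when a label applies) and `status` (`"ratio"` or the
#'   dominance label).
#' @export
#' @examples
#' icer(131, 0.011)
#' icer(-5, 0.02)
icer <- function(delta_cost, delta_qaly) {
  status <- dplyr::case_when(
    delta_cost < 0 & delta_qaly > 0 ~ "dominant",
    delta_cost > 0 & delta_qaly < 0 ~ "dominated",
    delta_cost == 0 & delta_qaly == 0 ~ "indifferent",
    delta_qaly == 0 & delta_cost > 0 ~ "+Inf",
    delta_qaly == 0 & delta_cost < 0 ~ "-Inf",
    .default = "ratio"
  )
  tibble::tibble(
    delta_cost = delta_cost,
    delta_qaly = delta_qaly,
    icer = ifelse(status == "ratio", delta_cost / delta_qaly, NA_real_),
    status = status
  )
}

#' Net monetary benefit
#'
#' `threshold * delta_qaly - delta_cost`, in GBP, at willingness-to-pay
#' `threshold` (GBP/QALY). Positive values favour the intervention.
#'
#' @param threshold Willingness-to-pay threshold(s), >= 0.
#' @param delta_cost Incremental cost (GBP).
#' @param delta_qaly Incremental QALYs.
#' @return Numeric net monetary benefit (vectorized with recycling).
#' @export
#' @examples
#' nmb(20000, 131, 0.011)
nmb <- function(threshold, delta_cost, delta_qaly) {
  if (any(threshold < 0)) abort("threshold must be non-negative")
  threshold * delta_qaly - delta_cost
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA iterations
#' with positive net monetary benefit.
#'
#' @param psa A `cea_psa` object ([run_psa()]).
#' @param thresholds Threshold grid (GBP/QALY); default GBP 0-50,000 in
#'   steps of 500, always including 20,000 and 30,000.
#' @return A tibble (`scenario`, `threshold`, `prob_ce`).
#' @export
ceac <- function(psa, thresholds = default_thresholds()) {
  if (length(thresholds) == 0L) abort("thresholds grid must be non-empty")
  inc <- psa_increments(psa)
  tidyr::expand_grid(
    scenario = unique(inc$scenario),
    threshold = sort(unique(thresholds))
  ) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      prob_ce = {
        d <- inc[inc$scenario == .data$scenario, , drop = FALSE]
        mean(nmb(.data$threshold, d$delta_cost, d$delta_qaly) > 0)
      }
    ) |>
    dplyr::ungroup()
}

#' Default willingness-to-pay threshold grid
#'
#' @return GBP 0 to 50,000 per QALY in steps of 500 (includes the
#'   conventional 20,000 and 30,000 decision thresholds).
#' @export
default_thresholds <- function() seq(0, 50000, by = 500)

#' Cost-effectiveness plane quadrant shares
#'
#' Classifies each iteration's (incremental QALY, incremental cost) pair
#' into the four quadrants of the cost-effectiveness plane. Axis-exact
#' points are assigned to the costlier / less-effective side (a zero QALY
#' difference counts as "not more effective"; a zero cost difference as
#' "not cheaper"), so shares always sum to 1.
#'
#' @param psa A `cea_psa` object.
#' @return A tibble (`scenario`, `quadrant`, `share`) with quadrants `NE`
#'   (more effective, costlier), `SE` (more effective, cheaper), `NW`
#'   (less effective, costlier), `SW` (less effective, cheaper).
#' @export
plane_quadrants <- function(psa) {
  inc <- psa_increments(psa)
  inc |>
    dplyr::mutate(
      quadrant = factor(
        dplyr::case_when(
          .data$delta_qaly > 0 & .data$delta_cost >= 0 ~ "NE",
          .data$delta_qaly > 0 & .data$delta_cost < 0 ~ "SE",
          .data$delta_qaly <= 0 & .data$delta_cost >= 0 ~ "NW",
          .default = "SW"
        ),
        levels = c("NE", "SE", "NW", "SW")
      )
    ) |>
    dplyr::count(.data$scenario, .data$quadrant, .drop = FALSE) |>
    dplyr::mutate(share = .data$n / sum(.data$n), .by = "scenario") |>
    dplyr::select("scenario", "quadrant", "share")
}

#' Summarize a PSA into decision metrics
#'
#' Per scenario: mean per-arm costs and QALYs across iterations; mean
#' incremental cost and QALYs with 95% intervals (both
#' percentile-across-iterations, the headline, and normal-theory
#' standard-error intervals); the ICER of the mean increments (ratio of
#' means, the convention consistent with reporting per-arm averages); net
#' monetary benefit of the means at each threshold with percentile and SE
#' intervals; the probability of cost-effectiveness at each threshold; and
#' the plane quadrant shares.
#'
#' @param psa A `cea_psa` object.
#' @param thresholds Thresholds (GBP/QALY) at which NMB and the
#'   probability of cost-effectiveness are reported.
#' @return A `cea_summary` object; `tidy()` returns the long table,
#'   `print()` shows a per-patient results table with scenarios as
#'   columns.
#' @export
summarize_psa <- function(psa, thresholds = c(20000, 30000)) {
  inc <- psa_increments(psa)
  arms <- psa$iterations |>
    dplyr::summarise(
      cost = mean(.data$cost), qaly = mean(.data$qaly),
      .by = c("scenario", "arm")
    )
  n <- psa$n_iter

  pct <- function(x, p) unname(quantile(x, p, names = FALSE))
  one <- function(sc) {
    d <- inc[inc$scenario == sc, , drop = FALSE]
    a <- arms[arms$scenario == sc, , drop = FALSE]
    dc <- mean(d$delta_cost)
    dq <- mean(d$delta_qaly)
    ic <- icer(dc, dq)
    rows <- list(tibble::tibble(
      scenario = sc,
      control_cost = a$cost[a$arm == "control"],
      intervention_cost = a$cost[a$arm == "intervention"],
      control_qaly = a$qaly[a$arm == "control"],
      intervention_qaly = a$qaly[a$arm == "intervention"],
      delta_cost = dc,
      delta_cost_lo = pct(d$delta_cost, 0.025),
      delta_cost_hi = pct(d$delta_cost, 0.975),
      delta_cost_se_lo = dc - 1.96 * sd(d$delta_cost) / sqrt(n),
      delta_cost_se_hi = dc + 1.96 * sd(d$delta_cost) / sqrt(n),
      delta_qaly = dq,
      delta_qaly_lo = pct(d$delta_qaly, 0.025),
      delta_qaly_hi = pct(d$delta_qaly, 0.975),
      delta_qaly_se_lo = dq - 1.96 * sd(d$delta_qaly) / sqrt(n),
      delta_qaly_se_hi = dq + 1.96 * sd(d$delta_qaly) / sqrt(n),
      icer = ic$icer,
      icer_status = ic$status
    ))
    for (th in thresholds) {
      nb <- nmb(th, d$delta_cost, d$delta_qaly)
      lab <- format(th, scientific = FALSE, trim = TRUE)
      thr <- tibble::tibble(
        !!paste0("nmb_", lab) := nmb(th, dc, dq),
        !!paste0("nmb_", lab, "_lo") := pct(nb, 0.025),
        !!paste0("nmb_", lab, "_hi") := pct(nb, 0.975),
        !!paste0("prob_ce_", lab) := mean(nb > 0)
      )
      rows <- c(rows, list(thr))
    }
    dplyr::bind_cols(rows)
  }
  table <- purrr::map(unique(inc$scenario), one) |> purrr::list_rbind()

  structure(
    list(
      table = table,
      thresholds = thresholds,
      quadrants = plane_quadrants(psa),
      n_iter = n,
      seed = psa$seed
    ),
    class = "cea_summary"
  )
}

#' @export
print.cea_summary <- function(x, digits = 3, ...) {
  tb <- x$table
  fmt_gbp <- function(v) paste0("GBP ", format(round(v), big.mark = ",", trim = TRUE))
  lines <- list(
    `Control arm NHS costs` = fmt_gbp(tb$control_cost),
    `Intervention arm NHS costs` = fmt_gbp(tb$intervention_cost),
    `Control arm QALYs` = format(round(tb$control_qaly, 3)),
    `Intervention arm QALYs` = format(round(tb$intervention_qaly, 3)),
    `Incremental costs (95% CI)` = paste0(
      fmt_gbp(tb$delta_cost), " (", round(tb$delta_cost_lo), " to ",
      round(tb$delta_cost_hi), ")"
    ),
    `Incremental QALYs (95% CI)` = paste0(
      round(tb$delta_qaly, 3), " (", round(tb$delta_qaly_lo, 3), " to ",
      round(tb$delta_qaly_hi, 3), ")"
    ),
    ICER = ifelse(tb$icer_status == "ratio",
      fmt_gbp(tb$icer), tb$icer_status
    )
  )
  for (th in x$thresholds) {
    lab <- format(th, scientific = FALSE, trim = TRUE)
    lines[[paste0("Probability cost-effective at GBP ", lab)]] <-
      format(round(tb[[paste0("prob_ce_", lab)]], 2))
    lines[[paste0("NMB at GBP ", lab, " (95% CI)")]] <- paste0(
      fmt_gbp(tb[[paste0("nmb_", lab)]]),
      " (", round(tb[[paste0("nmb_", lab, "_lo")]]), " to ",
      round(tb[[paste0("nmb_", lab, "_hi")]]), ")"
    )
  }
  out <- do.call(rbind, lines)
  colnames(out) <- tb$scenario
  cat("Per-patient lifetime cost-effectiveness (", x$n_iter,
    " PSA iterations)\n\n",
    sep = ""
  )
  print(out, quote = FALSE)
  invisible(x)
}

#' @rdname summarize_psa
#' @param x A `cea_summary` object.
#' @param ... Unused.
#' @method tidy cea_summary
#' @export
tidy.cea_summary <- function(x, ...) {
  x$table |>
    tidyr::pivot_longer(-c("scenario", "icer_status"),
      names_to = "quantity", values_to = "value"
    )
}

#' @rdname summarize_psa
#' @method glance cea_summary
#' @export
glance.cea_summary <- function(x, ...) {
  tibble::tibble(
    n_iter = x$n_iter,
    n_scenarios = nrow(x$table),
    seed = x$seed
  )
}
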