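# Validation and plain-text (CSV + YAML) serialization of parameter sets.
# Generated and loaded parameter sets satisfy the same contract; loading
# re-validates and fails naming the offending file/row.

#' Validate a parameter set
#'
#' Checks the structural contract every downstream module assumes:
#' probabilities in \[0, 1\]; standard errors non-negative; costs
#' non-negative; incidence shares summing to 1 within each (sex, age band);
#' total secondary-event risk per originating state not exceeding 1;
#' living-state utility multipliers in (0, 1\] with the unstable angina
#' multiplier equal to 90% of the stable angina multiplier and post-event
#' multipliers never below their acute event's; life-table probabilities
#' non-decreasing in age; positive SMR and non-negative discount rate.
#'
#' @param params A `cea_parameters` object ([generate_parameter_set()] or
#'   [load_parameter_set()]).
#' @return A tibble of violations (`table`, `where`, `issue`); zero rows if
#'   valid.
#' @export
validate_parameter_set <- function(params) {
  v <- list()
  bad <- function(table, where, issue) {
    tibble::tibble(table = table, where = where, issue = issue)
  }
  chk_range <- function(df, table, col, lo = 0, hi = 1) {
    x <- df[[col]]
    i <- which(!is.finite(x) | x < lo | x > hi)
    if (length(i) > 0L) {
      list(bad(table, paste0("row ", paste(i, collapse = ",")), paste0(
        "'", col, "' outside [", lo, ", ", hi, "]"
      )))
    } else {
      list()
    }
  }

  v <- c(v, chk_range(params$state_costs, "state_costs", "mean_gbp", 0, Inf))
  v <- c(v, chk_range(params$state_costs, "state_costs", "se_gbp", 0, Inf))
  v <- c(v, chk_range(params$state_utilities, "state_utilities", "multiplier_mean"))
  v <- c(v, chk_range(params$state_utilities, "state_utilities", "multiplier_se", 0, Inf))
  v <- c(v, chk_range(params$norms, "norms", "utility"))
  v <- c(v, chk_range(params$incidence, "incidence", "share"))
  v <- c(v, chk_range(params$secondary, "secondary", "prob"))
  v <- c(v, chk_range(params$case_fatality, "case_fatality", "prob"))
  v <- c(v, chk_range(params$life_table, "life_table", "qx"))
  v <- c(v, chk_range(params$growth, "growth", "growth_rate", -1, 1))

  # Living-state multipliers strictly positive.
  ut <- params$state_utilities
  dead_like <- grepl("death", ut$state)
  zero_live <- which(!dead_like & ut$multiplier_mean <= 0)
  if (length(zero_live) > 0L) {
    v <- c(v, list(bad(
      "state_utilities", paste0("state ", paste(ut$state[zero_live], collapse = ",")),
      "living-state utility multiplier must be in (0, 1]"
    )))
  }

  # Unstable angina multiplier = 0.9 x stable angina.
  if (all(c("stable_angina", "unstable_angina") %in% ut$state)) {
    sa <- ut$multiplier_mean[ut$state == "stable_angina"]
    ua <- ut$multiplier_mean[ut$state == "unstable_angina"]
    if (abs(ua - 0.9 * sa) > 1e-6) {
      v <- c(v, list(bad(
        "state_utilities", "state unstable_angina",
        paste0("unstable angina multiplier ", ua, " != 0.9 x stable (", 0.9 * sa, ")")
      )))
    }
  }

  # Post-event multipliers never below their acute event's.
  post_pairs <- tibble::tribble(
    ~post, ~acute,
    "post_ami", "ami",
    "post_tia", "tia",
    "post_stroke", "stroke"
  )
  for (i in seq_len(nrow(post_pairs))) {
    p <- post_pairs$post[i]
    a <- post_pairs$acute[i]
    if (all(c(p, a) %in% ut$state)) {
      if (ut$multiplier_mean[ut$state == p] <
        ut$multiplier_mean[ut$state == a] - 1e-12) {
        v <- c(v, list(bad(
          "state_utilities", paste0("state ", p),
          paste0("post-event multiplier below acute '", a, "'")
        )))
      }
    }
  }

  # Incidence shares normalized per (sex, age band).
  inc <- params$incidence |>
    dplyr::summarise(total = sum(.data$share), .by = c("sex", "age_band"))
  off <- inc[abs(inc$total - 1) > 1e-8, , drop = FALSE]
  if (nrow(off) > 0L) {
    v <- c(v, list(bad(
      "incidence",
      paste0(off$sex, "/", off$age_band, collapse = "; "),
      paste0(
        "shares sum to ",
        paste(signif(off$total, 8), collapse = ", "), ", not 1"
      )
    )))
  }

  # Secondary totals per originating state must not exceed 1.
  sec <- params$secondary |>
    dplyr::summarise(
      total = sum(.data$prob),
      .by = c("sex", "age_band", "from_state")
    )
  off <- sec[sec$total > 1 + 1e-12, , drop = FALSE]
  if (nrow(off) > 0L) {
    v <- c(v, list(bad(
      "secondary",
      paste0(off$sex, "/", off$age_band, "/", off$from_state, collapse = "; "),
      "total secondary-event probability exceeds 1"
    )))
  }

  # Life table non-decreasing in age within sex.
  lt <- params$life_table |> dplyr::arrange(.data$sex, .data$age)
  dec <- lt |>
    dplyr::mutate(drop = .data$qx < dplyr::lag(.data$qx) - 1e-12, .by = "sex") |>
    dplyr::filter(.data$drop %in% TRUE)
  if (nrow(dec) > 0L) {
    v <- c(v, list(bad(
      "life_table",
      paste0(dec$sex, "/age ", dec$age, collapse = "; "),
      "death probability decreases with age"
    )))
  }

  if (!is.finite(params$smr_mean) || params$smr_mean <= 0) {
    v <- c(v, list(bad("scalars", "smr_mean", "SMR must be positive")))
  }
  if (!is.finite(params$smr_se) || params$smr_se < 0) {
    v <- c(v, list(bad("scalars", "smr_se", "SMR se must be non-negative")))
  }
  if (!is.finite(params$discount_rate) || params$discount_rate < 0) {
    v <- c(v, list(bad("scalars", "discount_rate", "discount rate must be >= 0")))
  }

  if (length(v) == 0L) {
    tibble::tibble(table = character(), where = character(), issue = character())
  } else {
    dplyr::bind_rows(v)
  }
}

param_files <- c(
  state_costs = "costs.csv",
  state_utilities = "utilities.csv",
  norms = "norms.csv",
  incidence = "incidence.csv",
  secondary = "secondary.csv",
  case_fatality = "case_fatality.csv",
  life_table = "lifetable.csv",
  growth = "growth.csv"
)

#' Write / load a parameter set as plain-text CSV tables
#'
#' Tables are written one CSV per component (`costs.csv`, `utilities.csv`,
#' `norms.csv`, `incidence.csv`, `secondary.csv`, `case_fatality.csv`,
#' `lifetable.csv`, `growth.csv`) plus `scalars.yaml` holding the SMR,
#' discount rate, threshold grid and angina split. Loading re-validates
#' via [validate_parameter_set()] and fails naming the offending table and
#' row, so generated and loaded parameter sets are interchangeable
#' downstream.
#'
#' @param params A `cea_parameters` object.
#' @param dir Directory to write to / read from.
#' @return `write_parameter_set()` returns `dir` invisibly;
#'   `load_parameter_set()` returns a `cea_parameters` object.
#' @export
write_parameter_set <- function(params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(param_files)) {
    readr::write_csv(params[[nm]], file.path(dir, param_files[[nm]]))
  }
  yaml::write_yaml(
    list(
      smr_mean = params$smr_mean,
      smr_se = params$smr_se,
      discount_rate = params$discount_rate,
      thresholds = as.numeric(params$thresholds),
      angina_stable_fraction = params$angina_stable_fraction
    ),
    file.path(dir, "scalars.yaml")
  )
  invisible(dir)
}

#' @rdname write_parameter_set
#' @export
load_parameter_set <- function(dir) {
  specs <- list(
    state_costs = readr::cols(
      state = "c", mean_gbp = "d", se_gbp = "d", provenance = "c"
    ),
    state_utilities = readr::cols(
      state = "c", multiplier_mean = "d", multiplier_se = "d", provenance = "c"
    ),
    norms = readr::cols(sex = "c", age_band = "c", utility = "d", provenance = "c"),
    incidence = readr::cols(
      sex = "c", age_band = "c", event = "c", share = "d", provenance = "c"
    ),
    secondary = readr::cols(
      sex = "c", age_band = "c", from_state = "c", to_state = "c",
      prob = "d", provenance = "c"
    ),
    case_fatality = readr::cols(
      event = "c", sex = "c", age_band = "c", prob = "d", provenance = "c"
    ),
    life_table = readr::cols(sex = "c", age = "d", qx = "d", provenance = "c"),
    growth = readr::cols(age = "d", growth_rate = "d", provenance = "c")
  )
  tabs <- list()
  for (nm in names(param_files)) {
    path <- file.path(dir, param_files[[nm]])
    if (!file.exists(path)) {
      abort(paste0("missing parameter table: ", path))
    }
    hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
    need <- setdiff(names(specs[[nm]]$cols), c("provenance", hdr))
    if (length(need) > 0L) {
      abort(paste0(
        "file '", param_files[[nm]], "': missing column(s) ",
        paste(need, collapse = ", ")
      ))
    }
    tab <- readr::read_csv(path, col_types = specs[[nm]])
    if (!"provenance" %in% names(tab)) tab$provenance <- NA_character_
    tabs[[nm]] <- tab
  }
  sc <- yaml::read_yaml(file.path(dir, "scalars.yaml"))
  params <- structure(
    c(tabs, list(
      smr_mean = sc$smr_mean,
      smr_se = sc$smr_se,
      discount_rate = sc$discount_rate,
      thresholds = as.numeric(unlist(sc$thresholds)),
      angina_stable_fraction = sc$angina_stable_fraction %||% 0.5
    )),
    class = "cea_parameters"
  )
  viol <- validate_parameter_set(params)
  if (nrow(viol) > 0L) {
    fn <- unname(param_files[viol$table])
    fn[is.na(fn)] <- viol$table[is.na(fn)]
    abort(paste0(
      "invalid parameter set in '", dir, "':\n",
      paste0("- ", fn, " [", viol$where, "]: ", viol$issue, collapse = "\n")
    ))
  }
  params
}

#' Load cohort strata from CSV
#'
#' Reads a `strata.csv` with the schema written by
#' [write_synthetic_inputs()] and checks that weights sum to 1 within each
#' arm and risks are probabilities.
#'
#' @param path Path to the strata CSV file.
#' @return A strata tibble (see [generate_cohort_strata()]).
#' @export
load_cohort_strata <- function(path) {
  strata <- readr::read_csv(path, col_types = readr::cols(
    arm = "c", sex = "c", age0 = "d", weight = "d",
    baseline_r10 = "d", followup_r10 = "d",
    year0_cost = "d", year0_qaly = "d",
    year0_cost_se = "d", year0_qaly_se = "d"
  ))
  w <- strata |> dplyr::summarise(total = sum(.data$weight), .by = "arm")
  off <- w[abs(w$total - 1) > 1e-8, , drop = FALSE]
  if (nrow(off) > 0L) {
    abort(paste0(
      "strata weights must sum to 1 per arm; arm(s) ",
      paste(off$arm, collapse = ", "), " sum to ",
      paste(signif(off$total, 8), collapse = ", ")
    ))
  }
  check_probability(strata$baseline_r10, "baseline_r10")
  check_probability(strata$followup_r10, "followup_r10")
  strata
}
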