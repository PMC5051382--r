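# Configuration and end-to-end orchestration: synthetic input file sets,
# a YAML run configuration, and a pipeline that writes the summary, CEAC
# and plane tables as CSV.

#' Default run configuration
#'
#' @param seed Integer seed for all randomness.
#' @param n_iter PSA iterations.
#' @param scenarios Duration-of-effect labels to run.
#' @param cohort_size Simulated cohort size (for exported traces; results
#'   are per patient).
#' @param input_dir Directory holding `strata.csv` and the parameter CSVs;
#'   `NULL` generates synthetic defaults in memory.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1L, n_iter = 1000,
                           scenarios = SCENARIO_LABELS,
                           cohort_size = 1000,
                           input_dir = NULL) {
  structure(
    list(
      seed = as.integer(seed),
      n_iter = as.integer(n_iter),
      scenarios = scenarios,
      cohort_size = cohort_size,
      input_dir = input_dir,
      currency = "GBP 2012/13"
    ),
    class = "run_config"
  )
}

#' Write / load a run configuration as YAML
#'
#' @param config A `run_config` list ([default_config()]).
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `load_config()`
#'   returns a validated `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- modifyList(unclass(default_config()), raw)
  # A relative input_dir is resolved against the config file's directory.
  if (!is.null(cfg$input_dir) && !grepl("^(/|[A-Za-z]:)", cfg$input_dir)) {
    cfg$input_dir <- normalizePath(
      file.path(dirname(path), cfg$input_dir),
      mustWork = FALSE
    )
  }
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(config) {
  if (config$n_iter < 1) abort("config: n_iter must be >= 1")
  scenario_duration(unlist(config$scenarios)) # errors on unknown labels
  if (config$cohort_size <= 0) abort("config: cohort_size must be positive")
  invisible(config)
}

#' Write a complete synthetic input file set
#'
#' Generates the cohort strata and the synthetic parameter set for `seed`
#' and writes them, with a matching `config.yaml`, to `outdir`. The file
#' set is schema-valid, deterministic per seed and sufficient to run the
#' full pipeline with no other inputs.
#'
#' @param seed Integer seed.
#' @param outdir Output directory (created if needed).
#' @param ... Passed to [generate_cohort_strata()].
#' @return `outdir`, invisibly.
#' @export
write_synthetic_inputs <- function(seed = 1L, outdir, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  strata <- generate_cohort_strata(seed = seed, ...)
  params <- generate_parameter_set(seed = seed)
  readr::write_csv(strata, file.path(outdir, "strata.csv"))
  write_parameter_set(params, outdir)
  # Relative input_dir keeps the file set relocatable and byte-identical
  # across machines; resolve it against the config's own directory.
  write_config(
    default_config(seed = seed, input_dir = "."),
    file.path(outdir, "config.yaml")
  )
  invisible(outdir)
}

#' Run the full analysis pipeline
#'
#' Loads (or generates) the inputs, runs the PSA for every configured
#' duration-of-effect scenario, and writes `summary.csv` (the per-scenario
#' results table), `ceac.csv` (scenario, threshold, prob_ce), `plane.csv`
#' (per-iteration increments) and `run_log.json` (seed, iteration count,
#' input digests, package version) to `outdir`.
#'
#' @param config A `run_config` ([default_config()]) or path to a YAML
#'   configuration.
#' @param outdir Output directory (created if needed).
#' @return The `cea_summary`, invisibly.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  if (is.character(config)) config <- load_config(config)
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  digests <- character()
  if (!is.null(config$input_dir)) {
    strata <- load_cohort_strata(file.path(config$input_dir, "strata.csv"))
    params <- load_parameter_set(config$input_dir)
    files <- list.files(config$input_dir, "\\.(csv|yaml)$", full.names = TRUE)
    digests <- tools::md5sum(files)
    names(digests) <- basename(files)
  } else {
    strata <- generate_cohort_strata(seed = config$seed)
    params <- generate_parameter_set(seed = config$seed)
  }

  scenarios <- unlist(config$scenarios)
  psa <- run_psa(
    strata, params,
    scenarios = scenarios,
    n_iter = config$n_iter, seed = config$seed
  )
  summary <- summarize_psa(psa)

  readr::write_csv(summary$table, file.path(outdir, "summary.csv"))
  readr::write_csv(
    ceac(psa, params$thresholds),
    file.path(outdir, "ceac.csv")
  )
  readr::write_csv(psa_increments(psa), file.path(outdir, "plane.csv"))
  jsonlite::write_json(
    list(
      seed = config$seed,
      n_iter = config$n_iter,
      scenarios = scenarios,
      currency = config$currency,
      input_digests = as.list(digests),
      package_version = as.character(utils::packageVersion("cvdcea"))
    ),
    file.path(outdir, "run_log.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(summary)
}
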