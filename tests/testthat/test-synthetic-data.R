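test_that("cohort strata reproduce the trial-level inputs", {
  strata <- generate_cohort_strata(seed = 1)
  expect_identical(nrow(strata), 4L)
  # 80% male in each arm; weights sum to 1 per arm.
  for (a in c("control", "intervention")) {
    sub <- strata[strata$arm == a, ]
    expect_equal(sub$weight[sub$sex == "male"], 0.80)
    expect_equal(sum(sub$weight), 1)
  }
  expect_equal(
    strata$baseline_r10[strata$arm == "control" & strata$sex == "male"],
    0.3159
  )
  expect_equal(
    strata$followup_r10[strata$arm == "intervention" & strata$sex == "female"],
    0.2784
  )
  expect_equal(strata$age0[strata$sex == "male"], c(67, 67))
  expect_equal(strata$age0[strata$sex == "female"], c(69, 69))
  # Year-0 increments equal the configured trial increments.
  ctrl <- strata[strata$arm == "control" & strata$sex == "male", ]
  intv <- strata[strata$arm == "intervention" & strata$sex == "male", ]
  expect_equal(intv$year0_cost - ctrl$year0_cost, 138)
  expect_equal(intv$year0_qaly - ctrl$year0_qaly, 0.012)
})

test_that("strata generation is deterministic per seed", {
  expect_identical(generate_cohort_strata(seed = 1), generate_cohort_strata(seed = 1))
  expect_identical(generate_cohort_strata(seed = 1), generate_cohort_strata(seed = 2))
})

test_that("age-distribution mode keeps weights normalized per arm", {
  strata <- generate_cohort_strata(age_sd = 4)
  expect_gt(nrow(strata), 4L)
  w <- strata |> dplyr::summarise(total = sum(weight), .by = arm)
  expect_equal(w$total, c(1, 1))
  expect_true(all(strata$age0 >= 40 & strata$age0 <= 74))
})

test_that("synthetic parameter set satisfies its structural contract", {
  params <- generate_parameter_set(seed = 1)
  expect_identical(nrow(validate_parameter_set(params)), 0L)

  # Incidence shares normalized to machine precision.
  sums <- params$incidence |>
    dplyr::summarise(s = sum(share), .by = c(sex, age_band))
  expect_true(all(abs(sums$s - 1) < 1e-12))

  ut <- params$state_utilities
  expect_equal(
    ut$multiplier_mean[ut$state == "unstable_angina"],
    0.9 * ut$multiplier_mean[ut$state == "stable_angina"]
  )
  expect_equal(params$discount_rate, 0.035)

  # Acute cost > post cost > event-free (0).
  co <- setNames(params$state_costs$mean_gbp, params$state_costs$state)
  expect_true(co[["ami"]] > co[["post_ami"]])
  expect_true(co[["stroke"]] > co[["post_stroke"]])
  expect_true(co[["tia"]] > co[["post_tia"]])
  expect_identical(unname(co[["event_free"]]), 0)

  # Post-event utility never below the acute event's.
  um <- setNames(ut$multiplier_mean, ut$state)
  expect_gte(um[["post_ami"]], um[["ami"]])
  expect_gte(um[["post_tia"]], um[["tia"]])
  expect_gte(um[["post_stroke"]], um[["stroke"]])

  # Life table increasing in age within sex.
  lt <- params$life_table |> dplyr::arrange(sex, age)
  expect_true(all(diff(lt$qx[lt$sex == "male"]) >= 0))
  expect_true(all(diff(lt$qx[lt$sex == "female"]) >= 0))

  # Every table carries a provenance tag.
  for (nm in c(
    "state_costs", "state_utilities", "norms", "incidence",
    "secondary", "case_fatality", "life_table", "growth"
  )) {
    expect_true(all(params[[nm]]$provenance == "synthetic-default"),
      label = paste("provenance of", nm)
    )
  }
})

test_that("parameter sets round-trip through CSV", {
  params <- generate_parameter_set(seed = 1)
  dir <- withr::local_tempdir()
  write_parameter_set(params, dir)
  back <- load_parameter_set(dir)
  for (nm in c(
    "state_costs", "state_utilities", "norms", "incidence",
    "secondary", "case_fatality", "life_table", "growth"
  )) {
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(params[[nm]]),
      label = nm
    )
  }
  expect_equal(back$smr_mean, params$smr_mean)
  expect_equal(back$discount_rate, params$discount_rate)
  expect_equal(back$thresholds, params$thresholds)
})

test_that("loading rejects broken tables and names the offender", {
  params <- generate_parameter_set(seed = 1)
  dir <- withr::local_tempdir()

  # Incidence row not summing to 1.
  p1 <- params
  p1$incidence$share[1] <- p1$incidence$share[1] * 0.8
  write_parameter_set(p1, dir)
  expect_error(load_parameter_set(dir), "incidence")

  # Utility multiplier out of range.
  p2 <- params
  p2$state_utilities$multiplier_mean[p2$state_utilities$state == "tia"] <- 1.2
  write_parameter_set(p2, dir)
  expect_error(load_parameter_set(dir), "utilities")

  # Missing column.
  write_parameter_set(params, dir)
  costs <- readr::read_csv(file.path(dir, "costs.csv"), show_col_types = FALSE)
  readr::write_csv(costs[setdiff(names(costs), "se_gbp")], file.path(dir, "costs.csv"))
  expect_error(load_parameter_set(dir), "se_gbp")
})

test_that("strata loader checks arm weights and probability ranges", {
  strata <- generate_cohort_strata()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(strata, path)
  expect_equal(as.data.frame(load_cohort_strata(path)), as.data.frame(strata))

  bad <- strata
  bad$weight[1] <- 0.5
  readr::write_csv(bad, path)
  expect_error(load_cohort_strata(path), "sum to 1")
})
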