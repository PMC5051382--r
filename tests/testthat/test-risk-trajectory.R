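test_that("ten-year to annual conversion matches the constant-hazard closed form", {
  expect_identical(annualize_risk(0), 0)
  expect_identical(annualize_risk(1), 1)
  # 1 - (1 - 0.3159)^(1/10), frozen from independent evaluation.
  expect_equal(annualize_risk(0.3159), 0.037253476517, tolerance = 1e-10)
  expect_error(annualize_risk(1.2), "\\[0, 1\\]")
})

test_that("annualize is monotone and inverse-consistent with the ten-year form", {
  r <- seq(0, 1, by = 0.01)
  p <- annualize_risk(r)
  expect_true(all(diff(p) > 0))
  expect_true(all(p[r > 0 & r < 1] < r[r > 0 & r < 1]))
  expect_equal(ten_year_risk(p), r, tolerance = 1e-10)
})

test_that("risk extrapolation follows the growth recurrence", {
  growth0 <- tibble::tibble(age = 40:84, growth_rate = 0)
  # Zero growth: constant after year 1.
  path <- extrapolate_r10(0.30, 0.31, 67, growth0, horizon = 5)
  expect_equal(path, c(0.30, rep(0.31, 5)))

  # Independent loop oracle with a non-trivial growth table.
  growth <- tibble::tibble(age = 40:84, growth_rate = 0.03 + 0.0002 * (40:84))
  path <- extrapolate_r10(0.3159, 0.3200, 67, growth, horizon = 33)
  g <- setNames(growth$growth_rate, growth$age)
  oracle <- numeric(34)
  oracle[1] <- 0.3159
  oracle[2] <- 0.3200
  for (t in 2:33) {
    a <- 67 + t
    oracle[t + 1] <- if (a < 85) {
      min(1, oracle[t] * (1 + g[[as.character(a)]]))
    } else {
      min(1, oracle[t] + 0.01)
    }
  }
  expect_equal(path, oracle, tolerance = 1e-12)
  expect_true(all(diff(path[-1]) >= 0)) # non-decreasing when g >= 0
})

test_that("risk is capped at 1 beyond age 84 and stays there", {
  growth <- tibble::tibble(age = 40:84, growth_rate = 0)
  path <- extrapolate_r10(0.995, 0.995, 84, growth, horizon = 5)
  expect_equal(path, c(0.995, 0.995, 1, 1, 1, 1))
  # Relative elderly growth variant also respects the cap.
  rel <- extrapolate_r10(0.999, 0.999, 84, growth, horizon = 5,
    elderly_growth = "relative"
  )
  expect_true(all(rel <= 1))
})

test_that("extrapolation errors on bad horizons and missing growth ages", {
  growth <- tibble::tibble(age = 40:50, growth_rate = 0.02)
  expect_error(extrapolate_r10(0.3, 0.3, 67, growth, horizon = 0), "horizon")
  expect_error(extrapolate_r10(0.3, 0.3, 67, growth, horizon = 5), "age 69")
})

test_that("duration-of-effect scenarios splice paths with midpoint smoothing", {
  intv <- c(0.30, 0.31, 0.32, 0.33, 0.34, 0.35)
  ctrl <- c(0.31, 0.33, 0.35, 0.37, 0.39, 0.41)
  # D = 2: years 1-2 intervention, year 3 averaged, year 4+ control.
  out <- apply_effect_scenario(intv, ctrl, 2)
  expect_equal(out, c(0.30, 0.31, 0.32, (0.33 + 0.37) / 2, 0.39, 0.41))
  # D = 1: smoothing lands in year 2.
  out1 <- apply_effect_scenario(intv, ctrl, 1)
  expect_equal(out1, c(0.30, 0.31, (0.32 + 0.35) / 2, 0.37, 0.39, 0.41))
  # Lifetime: identity.
  expect_identical(apply_effect_scenario(intv, ctrl, Inf), intv)
  # Equal paths: identity for every duration.
  for (d in c(1, 2, 5)) {
    expect_equal(apply_effect_scenario(ctrl, ctrl, d), ctrl)
  }
  expect_error(apply_effect_scenario(intv, ctrl[-1], 2), "equal length")
})

test_that("longer effect never raises risk when intervention risk is lower", {
  set.seed(7)
  for (rep in 1:20) {
    n <- 30
    ctrl <- sort(runif(n, 0.2, 0.9))
    intv <- pmax(0, ctrl - runif(n, 0, 0.05))
    durations <- c(1, 2, 5, Inf)
    paths <- lapply(durations, function(d) apply_effect_scenario(intv, ctrl, d))
    for (i in seq_len(length(durations) - 1)) {
      expect_true(all(paths[[i + 1]] <= paths[[i]] + 1e-12))
    }
  }
})

test_that("event splitting is proportional and conserves the annual probability", {
  params <- default_fixture()$params
  p <- split_events(0.04, age = 67, sex = "male", params = params)
  expect_setequal(
    names(p),
    c("ami", "stable_angina", "unstable_angina", "tia", "stroke")
  )
  expect_equal(sum(p), 0.04, tolerance = 1e-12)
  shares <- params$incidence |>
    dplyr::filter(sex == "male", age_band == "65-74")
  expect_equal(unname(p[shares$event]), 0.04 * shares$share)
  expect_equal(unname(split_events(0, 70, "female", params)), rep(0, 5))
  # Random rows: outputs always sum to the input.
  set.seed(11)
  for (rep in 1:20) {
    pa <- runif(1)
    age <- sample(40:99, 1)
    sx <- sample(c("male", "female"), 1)
    expect_equal(sum(split_events(pa, age, sx, params)), pa, tolerance = 1e-12)
  }
})

test_that("full trajectories are reproducible and respect arm structure", {
  fx <- default_fixture()
  traj <- risk_trajectories(fx$strata, fx$params)
  # Control path identical across scenarios.
  ctrl <- traj |> dplyr::filter(arm == "control", sex == "male")
  wide <- ctrl |>
    tidyr::pivot_wider(names_from = scenario, values_from = c(r10, p_annual))
  expect_equal(wide$r10_1y, wide$r10_lifetime)
  # Intervention under lifetime effect differs from 1y beyond year 1.
  intv <- traj |> dplyr::filter(arm == "intervention", sex == "male")
  i1 <- intv$r10[intv$scenario == "1y"]
  ilt <- intv$r10[intv$scenario == "lifetime"]
  expect_false(isTRUE(all.equal(i1, ilt)))
  # p_annual below r10 wherever risk is interior.
  interior <- traj$r10 > 0 & traj$r10 < 1
  expect_true(all(traj$p_annual[interior] < traj$r10[interior]))
})
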