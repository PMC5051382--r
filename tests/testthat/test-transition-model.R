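test_that("non-CVD death probability is the SMR-scaled life-table rate, capped", {
  params <- default_fixture()$params
  params$life_table$qx[params$life_table$sex == "male" &
    params$life_table$age == 70] <- 0.02
  expect_equal(noncvd_death_prob(70, "male", params, smr = 1), 0.02)
  expect_equal(noncvd_death_prob(70, "male", params, smr = 0.8), 0.016)
  params$life_table$qx[params$life_table$sex == "male" &
    params$life_table$age == 70] <- 0.9
  expect_equal(noncvd_death_prob(70, "male", params, smr = 1.5), 1)
  expect_error(noncvd_death_prob(200, "male", params), "life table")
  expect_error(noncvd_death_prob(70, "male", params, smr = 0), "positive")
})

test_that("cycle table reproduces the hand-computed competing-risk products", {
  fx <- default_fixture()
  params <- fx$params
  # Pin the inputs of the worked example: qx = 0.01, AMI case fatality 0.3.
  params$life_table$qx[params$life_table$sex == "male" &
    params$life_table$age == 67] <- 0.01
  params$case_fatality$prob[params$case_fatality$event == "ami" &
    params$case_fatality$sex == "male" &
    params$case_fatality$age_band == "65-74"] <- 0.3
  space <- expanded_state_space(fx$reg)
  pp <- c(ami = 0.02, stable_angina = 0, unstable_angina = 0, tia = 0, stroke = 0)
  M <- build_cycle_table(space, age = 67, sex = "male", primary_probs = pp,
    params = params, smr = 1
  )
  # Non-CVD death first, then fatal/non-fatal split of the event.
  expect_equal(M["event_free", "cvd_death"], 0.99 * 0.02 * 0.3) # 0.00594
  expect_equal(M["event_free", "ami.1"], 0.99 * 0.02 * 0.7) # 0.01386
  expect_equal(M["event_free", "noncvd_death"], 0.01)
  expect_equal(M["event_free", "event_free"], 0.99 * 0.98)
})

test_that("every assembled row is stochastic and confined to permitted transitions", {
  fx <- default_fixture()
  space <- expanded_state_space(fx$reg)
  labels <- space$nodes$label
  permitted <- matrix(FALSE, length(labels), length(labels),
    dimnames = list(labels, labels)
  )
  for (i in seq_len(nrow(space$edges))) {
    permitted[space$edges$from[i], space$edges$to[i]] <- TRUE
  }
  dead <- labels[space$nodes$category == "dead"]
  for (d in dead) permitted[d, d] <- TRUE

  set.seed(3)
  for (rep in 1:10) {
    age <- sample(45:99, 1)
    sx <- sample(c("male", "female"), 1)
    p_any <- runif(1, 0, 0.3)
    pp <- split_events(p_any, age, sx, fx$params)
    M <- build_cycle_table(space, age, sx, pp, fx$params,
      smr = runif(1, 0.5, 1.5)
    )
    expect_equal(unname(rowSums(M)), rep(1, nrow(M)), tolerance = 1e-10)
    expect_true(all(M >= 0 & M <= 1))
    expect_true(all(M[!permitted] == 0))
  }
})

test_that("transition tables conserve probability mass", {
  fx <- default_fixture()
  space <- expanded_state_space(fx$reg)
  pp <- split_events(0.05, 70, "male", fx$params)
  M <- build_cycle_table(space, 70, "male", pp, fx$params, smr = 0.9)
  set.seed(5)
  for (rep in 1:5) {
    occ <- runif(nrow(M))
    expect_equal(sum(occ %*% M), sum(occ), tolerance = 1e-10)
  }
})

test_that("null dynamics freeze every state except the acute-year transition", {
  fx <- default_fixture()
  params <- fx$params
  params$life_table$qx <- 0
  params$secondary$prob <- 0
  space <- expanded_state_space(fx$reg)
  pp <- setNames(rep(0, 5), c(
    "ami", "stable_angina", "unstable_angina", "tia", "stroke"
  ))
  M <- build_cycle_table(space, 67, "male", pp, params, smr = 1)
  post_of <- cvdcea:::post_state_map(fx$reg$states)
  nodes <- space$nodes
  for (i in seq_len(nrow(nodes))) {
    if (nodes$category[i] == "acute" && !nodes$chronic[i]) {
      # Acute states last exactly one cycle, then their post state.
      dest <- paste0(post_of[[nodes$state[i]]], ".", nodes$count[i])
      expect_equal(unname(M[nodes$label[i], dest]), 1)
    } else {
      expect_equal(unname(M[nodes$label[i], nodes$label[i]]), 1)
    }
  }
})

test_that("without mortality or case fatality no mass reaches death before age 100", {
  fx <- default_fixture()
  params <- fx$params
  params$life_table$qx <- 0
  params$case_fatality$prob <- 0
  mt <- model_tables(fx$strata, params, "control", "male", "lifetime", smr = 1)
  meta <- cvdcea:::space_meta(mt$space)
  initial <- setNames(numeric(meta$S), meta$labels)
  initial[meta$ef] <- 1
  trace <- run_trace(initial, mt$tables)
  dead_mass <- rowSums(trace[, c("cvd_death", "noncvd_death"), drop = FALSE])
  expect_true(all(dead_mass < 1e-12))
})

test_that("raising one event probability increases flow into that event", {
  fx <- default_fixture()
  space <- expanded_state_space(fx$reg)
  base <- split_events(0.05, 70, "male", fx$params)
  up <- base
  up["stroke"] <- up["stroke"] + 0.02
  M0 <- build_cycle_table(space, 70, "male", base, fx$params, smr = 1)
  M1 <- build_cycle_table(space, 70, "male", up, fx$params, smr = 1)
  expect_gt(M1["event_free", "stroke.1"], M0["event_free", "stroke.1"])
})

test_that("at age 100 and beyond all surviving mass is sent to non-CVD death", {
  fx <- default_fixture()
  space <- expanded_state_space(fx$reg)
  pp <- split_events(0.1, 100, "male", fx$params)
  M <- build_cycle_table(space, 100, "male", pp, fx$params, smr = 1)
  living <- space$nodes$label[space$nodes$category != "dead"]
  expect_true(all(M[living, "noncvd_death"] == 1))
  expect_equal(unname(rowSums(M)), rep(1, nrow(M)))
})

test_that("overloaded event probabilities fail loudly instead of rescaling", {
  fx <- default_fixture()
  space <- expanded_state_space(fx$reg)
  pp <- setNames(rep(0.3, 5), c(
    "ami", "stable_angina", "unstable_angina", "tia", "stroke"
  ))
  expect_error(
    build_cycle_table(space, 67, "male", pp, fx$params, smr = 1),
    "refusing to rescale"
  )
})
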