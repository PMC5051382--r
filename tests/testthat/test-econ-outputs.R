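test_that("ICER handles ratios, dominance and degenerate cases", {
  r <- icer(131, 0.011)
  expect_equal(r$icer, 131 / 0.011) # 11909.09...
  expect_identical(r$status, "ratio")
  expect_identical(icer(-5, 0.02)$status, "dominant")
  expect_identical(icer(50, -0.01)$status, "dominated")
  expect_identical(icer(0, 0)$status, "indifferent")
  expect_identical(icer(10, 0)$status, "+Inf")
  expect_identical(icer(-10, 0)$status, "-Inf")
  # Vectorized.
  v <- icer(c(131, -5), c(0.011, 0.02))
  expect_identical(v$status, c("ratio", "dominant"))
})

test_that("net monetary benefit follows threshold x dQ - dC", {
  expect_equal(nmb(20000, 131, 0.011), 89)
  expect_equal(nmb(0, 131, 0.011), -131)
  expect_equal(nmb(20000, 0, 0), 0)
  expect_error(nmb(-1, 0, 0), "non-negative")
})

test_that("the CEAC counts iterations with positive net benefit", {
  # Four iterations engineered to give NMB signs (+, +, -, -) at 20k.
  psa <- fake_psa(
    delta_cost = c(100, -50, 300, 500),
    delta_qaly = c(0.010, 0.001, 0.010, -0.010)
  )
  cc <- ceac(psa, thresholds = 20000)
  expect_equal(cc$prob_ce, 0.5)
  # All dominant: probability 1 at every threshold.
  psa2 <- fake_psa(delta_cost = rep(-10, 4), delta_qaly = rep(0.01, 4))
  cc2 <- ceac(psa2, thresholds = c(0, 10000, 30000))
  expect_equal(cc2$prob_ce, rep(1, 3))
  expect_error(ceac(psa, thresholds = numeric()), "non-empty")
})

test_that("CEAC limits recover the cost and QALY sign fractions", {
  set.seed(8)
  n <- 400
  psa <- fake_psa(
    delta_cost = rnorm(n, 50, 200),
    delta_qaly = rnorm(n, 0.01, 0.02)
  )
  inc <- psa_increments(psa)
  cc0 <- ceac(psa, thresholds = 0)
  expect_equal(cc0$prob_ce, mean(inc$delta_cost < 0))
  cc_inf <- ceac(psa, thresholds = 1e9)
  expect_equal(cc_inf$prob_ce, mean(inc$delta_qaly > 0), tolerance = 0.01)
})

test_that("CEAC matches the analytic normal tail probability", {
  set.seed(12)
  n <- 1000
  mu_c <- 120
  sd_c <- 80
  mu_q <- 0.012
  sd_q <- 0.005
  psa <- fake_psa(rnorm(n, mu_c, sd_c), rnorm(n, mu_q, sd_q))
  lambda <- 20000
  # NMB ~ normal(lambda mu_q - mu_c, sqrt(lambda^2 sd_q^2 + sd_c^2)).
  p_true <- pnorm(0, lambda * mu_q - mu_c,
    sqrt(lambda^2 * sd_q^2 + sd_c^2),
    lower.tail = FALSE
  )
  p_hat <- ceac(psa, thresholds = lambda)$prob_ce
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("plane quadrant shares sum to 1 and follow the axis convention", {
  psa <- fake_psa(
    delta_cost = c(10, -10, 10, -10, 0),
    delta_qaly = c(0.01, 0.01, -0.01, -0.01, 0)
  )
  q <- plane_quadrants(psa)
  expect_equal(sum(q$share), 1)
  shares <- setNames(q$share, as.character(q$quadrant))
  # The (0, 0) point goes to the costlier/less-effective side: NW.
  expect_equal(unname(shares["NW"]), 2 / 5)
  expect_equal(unname(shares[c("NE", "SE", "SW")]), c(1, 1, 1) / 5)

  # All strictly NE.
  q2 <- plane_quadrants(fake_psa(rep(5, 10), rep(0.01, 10)))
  expect_equal(q2$share[q2$quadrant == "NE"], 1)

  # Symmetric cloud: ~1/4 in each quadrant.
  set.seed(21)
  n <- 4000
  q3 <- plane_quadrants(fake_psa(rnorm(n), rnorm(n)))
  expect_true(all(abs(q3$share - 0.25) < 3 * sqrt(0.25 * 0.75 / n)))
})

test_that("summaries collapse for degenerate PSAs and report means-based ICERs", {
  psa <- fake_psa(rep(100, 3), rep(0.01, 3))
  s <- summarize_psa(psa)
  tb <- s$table
  expect_equal(tb$delta_cost, 100)
  expect_equal(tb$delta_cost_lo, 100)
  expect_equal(tb$delta_cost_hi, 100)
  expect_equal(tb$icer, 10000)
  expect_equal(tb$nmb_20000, 20000 * 0.01 - 100)
  expect_equal(tb$prob_ce_20000, 1)

  # Null intervention: indifferent, zero NMB.
  s0 <- summarize_psa(fake_psa(rep(0, 3), rep(0, 3)))
  expect_identical(s0$table$icer_status, "indifferent")
  expect_equal(s0$table$nmb_20000, 0)
})

test_that("NMB of the means changes sign at the mean-based ICER", {
  set.seed(31)
  psa <- fake_psa(rnorm(200, 120, 50), rnorm(200, 0.012, 0.004))
  s <- summarize_psa(psa)
  ic <- s$table$icer
  inc <- psa_increments(psa)
  dc <- mean(inc$delta_cost)
  dq <- mean(inc$delta_qaly)
  expect_lt(nmb(ic * 0.99, dc, dq), 0)
  expect_gt(nmb(ic * 1.01, dc, dq), 0)
  expect_equal(nmb(ic, dc, dq), 0, tolerance = 1e-9)
})

test_that("percentile intervals cover the true mean increment about 95% of the time", {
  set.seed(41)
  reps <- 120
  n <- 200
  mu <- 100
  hits <- 0
  for (r in seq_len(reps)) {
    d <- rnorm(n, mu, 150)
    lo <- quantile(d, 0.025, names = FALSE)
    hi <- quantile(d, 0.975, names = FALSE)
    # The percentile interval is for the iteration distribution; coverage
    # of the true mean by +-1.96 SE is the sharper check.
    se_lo <- mean(d) - 1.96 * sd(d) / sqrt(n)
    se_hi <- mean(d) + 1.96 * sd(d) / sqrt(n)
    if (se_lo <= mu && mu <= se_hi) hits <- hits + 1
    expect_lt(lo, hi)
  }
  expect_gt(hits / reps, 0.88)
  expect_lt(hits / reps, 0.995)
})

test_that("summary tidier exposes every reported quantity in long form", {
  psa <- fake_psa(rnorm(50, 100, 10), rnorm(50, 0.01, 0.001))
  s <- summarize_psa(psa, thresholds = c(20000, 30000))
  long <- tidy(s)
  expect_true(all(c("scenario", "quantity", "value") %in% names(long)))
  expect_true("prob_ce_30000" %in% long$quantity)
  g <- glance(s)
  expect_identical(g$n_iter, 50L)
})
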