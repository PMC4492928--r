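test_that("1880 double-power law: anchors, limits and domain", {
  # (2/t)^a1 = 1 at t = 2 forces the inner bracket to 0, so Q -> 1
  # (the approach is slow: the inner bracket vanishes like (t - 2))
  expect_equal(q_eb1880(2 + 1e-9, 0.7, 0.2), 1, tolerance = 1e-4)
  expect_equal(q_eb1880(2 + 1e-9, 0.51, 0.099), 1, tolerance = 1e-4)
  # direct scalar evaluation at the classical parameter values
  expect_equal(q_eb1880(525, 0.523, 0.101), 0.3566499, tolerance = 1e-6)
  expect_equal(q_eb1880(44640, 0.523, 0.101), 0.2105881, tolerance = 1e-6)
  # Q -> 0 as t -> Inf, at the slow rate set by the small inner exponent
  expect_lt(q_eb1880(1e30, 0.523, 0.101), 1e-3)
  expect_error(q_eb1880(2, 0.5, 0.1), "2 minute")
  expect_error(q_eb1880(1.5, 0.5, 0.1), "2 minute")
})

test_that("1885 logarithmic law: Q(1) = 1 exactly, known values, domain", {
  expect_identical(q_eb1885(1, 1.84, 1.25), 1)
  expect_identical(q_eb1885(1, 0.3, 2), 1)
  expect_equal(q_eb1885(19, 1.8, 1.21), 0.5720610, tolerance = 1e-6)
  expect_equal(q_eb1885(1440, 1.8, 1.21), 0.3092179, tolerance = 1e-6)
  expect_error(q_eb1885(0.5, 1.8, 1.21), "1 minute")
})

test_that("power laws: intercepts and reference values", {
  expect_equal(q_power(0, 1.23, 0.2), 1.23)
  expect_equal(q_power(518400, 1.4, 0.13), 0.2530588, tolerance = 1e-6)
  expect_equal(q_power(32400, 0.965, 0.0926), 0.3688498, tolerance = 1e-6)
  expect_equal(q_power_printed(0, 3, 0.4), 1)
  # boost: plain power below one day, constant jump at and beyond it
  t <- c(1200, 86399, 86400, 518400)
  expect_equal(q_power_boost(t, 1.4, 0.13, 0),
               q_power(t, 1.4, 0.13))
  expect_equal(q_power_boost(86400, 1.4, 0.13, 0.131) -
                 q_power_boost(86399, 1.4, 0.13, 0.131),
               0.131 + q_power(86400, 1.4, 0.13) - q_power(86399, 1.4, 0.13))
  expect_equal(q_power_boost(518400, 1.65, 0.152, 0.0303), 0.2535825,
               tolerance = 1e-6)
})

test_that("exponential laws: intercepts, half-life, reference values", {
  expect_equal(q_summed_exp(0, 0.4, 1e-4, 0.3, 1e-7), 0.7)
  expect_equal(q_summed_exp(1140, 0.383, 0.000319, 0.321, 1.79e-7),
               0.5871683, tolerance = 1e-6)
  expect_equal(q_summed_exp(2678400, 0.383, 0.000319, 0.321, 1.79e-7),
               0.1987420, tolerance = 1e-6)
  expect_equal(q_mcm(0, 0.704, 3e-4, 1e-4, 1e-7), 0.704)
  expect_equal(q_mcm(1140, 0.704, 0.000319, 0.000145, 1.79e-7),
               0.5869184, tolerance = 1e-6)
  expect_equal(q_single_exp(0, 0.9, 1e-5), 0.9)
  expect_equal(q_single_exp(1e6, 0.9, 0), rep(0.9, 1))
  a1 <- 3e-4
  expect_equal(q_single_exp(log(2) / a1, 0.8, a1), 0.4)
})

test_that("memory-chain degenerate branch matches the analytic limit", {
  # exactly equal rates: closed-form limit mu1 e^(-a1 t) (1 + mu2 t)
  expect_equal(q_mcm(1000, 0.5, 1e-3, 1e-4, 1e-3),
               0.5 * exp(-1) * 1.1, tolerance = 1e-12)
  # just outside the switching threshold the two-branch formula agrees
  # with the limit branch; the achievable agreement is set by the
  # cancellation in exp(-a2 t) - exp(-a1 t) at a rate gap of ~1e-11
  # relative, so the tolerance is ~sqrt(machine eps), not tighter
  a1 <- 2e-4
  for (mult in c(10, 100)) {
    a2 <- a1 * (1 - mult * 1e-12)
    t <- c(0, 1e3, 1e5, 2.7e6)
    exact <- 0.6 * exp(-a1 * t) + 0.6 * 3e-4 * (exp(-a2 * t) - exp(-a1 * t)) /
      (a1 - a2)
    limit <- 0.6 * exp(-a1 * t) * (1 + 3e-4 * t)
    expect_equal(q_mcm(t, 0.6, a1, 3e-4, a2), exact, tolerance = 2e-6)
    expect_equal(exact, limit, tolerance = 2e-6)
  }
})

test_that("all retention laws are non-increasing in time", {
  set.seed(11)
  grids <- list(
    min = exp(seq(log(2.001), log(45000), length.out = 100)),
    sec = exp(seq(log(1), log(3e6), length.out = 100))
  )
  for (i in 1:20) {
    a1 <- 10^runif(1, -5, -3)
    a2 <- 10^runif(1, -8, -6)
    pars <- list(
      eb1880 = c(runif(1, 0.1, 2), runif(1, 0.02, 0.5)),
      eb1885 = c(runif(1, 0.3, 5), runif(1, 0.3, 2)),
      power = c(runif(1, 0.3, 3), runif(1, 0.05, 0.3)),
      power_boost = c(runif(1, 0.3, 3), runif(1, 0.05, 0.3), runif(1, 0, 0.3)),
      summed_exp = c(runif(1, 0.1, 1), a1, runif(1, 0.1, 1), a2),
      # consolidation below the net fast-store decay keeps the memory-chain
      # curve monotone (otherwise it may rise before it falls)
      mcm = c(runif(1, 0.1, 1), a1, runif(1, 0, 0.9) * (a1 - a2), a2),
      single_exp = c(runif(1, 0.1, 1), 10^runif(1, -7, -5))
    )
    for (m in names(pars)) {
      unit <- if (m %in% c("eb1880", "eb1885")) "min" else "sec"
      grid <- grids[[unit]] * (if (unit == "min") 60 else 1)
      q <- retention_q(m, grid, pars[[m]])
      dq <- diff(q)
      if (m == "power_boost") {
        # exclude the single upward step at the one-day boundary
        dq <- dq[!(grid[-1] >= 86400 & grid[-length(grid)] < 86400)]
      }
      expect_true(all(dq <= 1e-12),
                  label = sprintf("%s non-increasing (draw %d)", m, i))
    }
  }
})

test_that("memory-chain model is a reparameterized summed exponential", {
  # identity on a reference parameter set, matching the published pairing
  b <- mcm_to_summed(0.704, 0.000319, 0.000145, 1.79e-7)
  expect_equal(unname(b), c(0.3838203, 0.3201797), tolerance = 1e-6)
  # no consolidation: collapses to the single exponential coefficients
  expect_equal(unname(mcm_to_summed(0.7, 1e-3, 0, 1e-6)), c(0.7, 0))
  expect_error(mcm_to_summed(0.7, 1e-3, 1e-4, 1e-3), "degenerate")
  # property: equality at random parameters and times
  set.seed(21)
  for (i in 1:1000) {
    mu1 <- runif(1, 0.05, 2); a1 <- 10^runif(1, -6, -3)
    mu2 <- 10^runif(1, -6, -3); a2 <- 10^runif(1, -9, -7)
    t <- 10^runif(1, 0, 6.5)
    b <- mcm_to_summed(mu1, a1, mu2, a2)
    lhs <- q_mcm(t, mu1, a1, mu2, a2)
    rhs <- q_summed_exp(t, b[["beta1"]], a1, b[["beta2"]], a2)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("unified evaluator converts seconds to the model's native unit", {
  expect_identical(retention_q("eb1885", 60, c(mu1 = 1.8, a1 = 1.21)), 1)
  expect_equal(retention_q("eb1880", 525 * 60, c(0.523, 0.101)),
               q_eb1880(525, 0.523, 0.101))
  expect_equal(retention_q("power", 1e4, c(a1 = 0.13, mu1 = 1.4)),
               q_power(1e4, 1.4, 0.13))  # named args may come in any order
  expect_error(retention_q("power", 100, c(1, 2, 3)), "2 parameters")
  expect_error(retention_q("power", 100, c(x = 1, y = 2)), "parameter names")
})
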