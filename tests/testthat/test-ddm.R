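test_that("drift is the stated control-weighted pathway mixture", {
  expect_equal(drift_from_control(1, +1, -1, 1.32, 3.22), 1.32)
  expect_equal(drift_from_control(0, +1, -1, 1.32, 3.22), -3.22)
  expect_equal(drift_from_control(0.5, +1, -1, 1.32, 3.22), -0.95)
  expect_equal(drift_from_control(0.25, -1, +1, 2, 4), -0.5 + 3)
  expect_error(drift_from_control(1.2))
})

test_that("analytic choice probability matches its closed form", {
  expect_equal(ddm_choice_probability(ddm_params(v = 0, a = 2)), 0.5)
  p <- ddm_params(v = 1, a = 2, z = 1, s = 1)
  expect_equal(ddm_choice_probability(p),
               (1 - exp(-2)) / (1 - exp(-4)), tolerance = 1e-12)
  # reflection symmetry: P_upper(v, z) = 1 - P_upper(-v, a - z)
  for (v in c(-2, -0.3, 0.7, 1.5)) {
    for (z in c(0.5, 1, 1.4)) {
      expect_equal(
        ddm_choice_probability(ddm_params(v = v, a = 2, z = z)),
        1 - ddm_choice_probability(ddm_params(v = -v, a = 2, z = 2 - z)),
        tolerance = 1e-10)
    }
  }
  # extreme drifts are numerically stable
  expect_equal(ddm_choice_probability(ddm_params(v = 500, a = 2)), 1)
  expect_lt(ddm_choice_probability(ddm_params(v = -500, a = 2)), 1e-100)
})

test_that("simulated choices and decision times match analytic oracles", {
  # symmetric zero-drift case
  d0 <- ddm_simulate(ddm_params(v = 0, a = 2, deadline = 20), 10000, seed = 1)
  expect_lt(abs(mean(d0$boundary == "upper") - 0.5), 3 * sqrt(0.25 / 10000))
  # drifted case against the absorption-probability formula (fine step so
  # discretization bias is below Monte-Carlo error)
  p <- ddm_params(v = 1, a = 2, z = 1, s = 1, deadline = 20, dt = 2e-4)
  d <- ddm_simulate(p, 10000, seed = 2)
  ph <- mean(d$boundary == "upper")
  pa <- ddm_choice_probability(p)
  expect_lt(abs(ph - pa), 3 * sqrt(pa * (1 - pa) / 10000))
  # mean decision time (z = a/2 closed form)
  dt_hat <- mean(d$rt - p$t0)
  dt_an <- ddm_mean_decision_time(p)
  expect_equal(dt_an, (p$a / (2 * p$v)) * tanh(p$v * p$a / (2 * p$s^2)))
  expect_lt(abs(dt_hat - dt_an), 3 * sd(d$rt) / sqrt(10000))
  # near-deterministic strong-drift limit: decision time -> (a - z)/v
  ps <- ddm_params(v = 50, a = 2, z = 1, s = 1, t0 = 0)
  ds <- ddm_simulate(ps, 2000, seed = 3)
  expect_equal(mean(ds$boundary == "upper"), 1)
  expect_equal(mean(ds$rt), (ps$a - ps$z) / ps$v, tolerance = 0.2)
})

test_that("first-passage density integrates to the choice probability", {
  for (v in c(-1.5, 0.4, 2)) {
    p <- ddm_params(v = v, a = 1.6, z = 0.8, s = 1, t0 = 0.25)
    up <- integrate(function(t) ddm_fpt_density(t, p, "upper"),
                    p$t0, Inf, rel.tol = 1e-9)$value
    lo <- integrate(function(t) ddm_fpt_density(t, p, "lower"),
                    p$t0, Inf, rel.tol = 1e-9)$value
    expect_equal(up, ddm_choice_probability(p), tolerance = 1e-4)
    expect_equal(lo, 1 - ddm_choice_probability(p), tolerance = 1e-4)
    expect_equal(ddm_fpt_density(p$t0 - 0.1, p, "upper"), 0)
  }
  # nonnegative on a parameter grid
  tt <- seq(0.26, 5, length.out = 60)
  for (v in c(-3, 0, 3)) {
    for (a in c(0.8, 2.5)) {
      p <- ddm_params(v = v, a = a, t0 = 0.25)
      expect_true(all(ddm_fpt_density(tt, p, "upper") >= 0))
      expect_true(all(ddm_fpt_density(tt, p, "lower") >= 0))
    }
  }
})

test_that("simulated response times follow the first-passage density", {
  p <- ddm_params(v = 1.2, a = 1.8, t0 = 0.3, deadline = 30, dt = 1e-4)
  sim <- ddm_simulate(p, 10000, seed = 11)
  rt_up <- sim$rt[sim$boundary == "upper" & !sim$timed_out]
  # conditional CDF of upper-boundary RTs from the density
  pu <- ddm_choice_probability(p)
  cdf <- function(q) {
    vapply(q, function(qi) {
      integrate(function(t) ddm_fpt_density(t, p, "upper"), p$t0, qi,
                rel.tol = 1e-8)$value / pu
    }, numeric(1))
  }
  ks <- suppressWarnings(stats::ks.test(rt_up, cdf))
  expect_gt(ks$p.value, 0.01)
})
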