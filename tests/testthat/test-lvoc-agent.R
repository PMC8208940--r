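test_that("featurization activates color, word, conjunction, global at c", {
  f <- lvoc_features("blue", "red", 0.6)
  expect_equal(sum(f != 0), 4)
  expect_equal(unname(f[f != 0]), rep(0.6, 4))
  expect_equal(unname(f[c("color_blue", "word_red", "conj_blue_red",
                           "global")]), rep(0.6, 4))
  expect_equal(sum(lvoc_features("blue", "red", 0) != 0), 0)
  f1 <- lvoc_features("green", "pink", 1)
  expect_equal(sum(f1 == 1), 4)
  expect_equal(sum(lvoc_features("green", "pink", 1,
                                 include_conjunctions = FALSE) != 0), 3)
  expect_error(lvoc_features("cyan", "red", 0.5), "unknown")
})

test_that("control cost matches its closed form and both variants", {
  expect_equal(control_cost(0, 0), 2 * exp(-1))
  expect_equal(control_cost(0, 0, cost_params(baseline_subtracted = TRUE)), 0)
  expect_equal(control_cost(1, 1), exp(-0.75) + exp(-1))
  # strictly increasing in |c_t| and in |c_t - c_prev|, both variants
  for (bs in c(FALSE, TRUE)) {
    cp <- cost_params(baseline_subtracted = bs)
    cs <- seq(0, 1, 0.1)
    expect_true(all(diff(control_cost(cs, 0, cp)) > 0))
    expect_true(all(diff(control_cost(1, 1 - cs, cp)) > 0))
  }
})

test_that("experienced value subtracts the opportunity cost of time", {
  expect_equal(experienced_value(10, 1.0), 9.56)
  expect_equal(experienced_value(0, 0), 0)
  expect_equal(experienced_value(5, 3.0), 3.68)
})

test_that("single conjugate update matches the textbook scalar case", {
  post <- lvoc_prior(mu_prior = 0, tau_prior = 1)
  f <- numeric(81)
  f[5] <- 1
  up <- update_posterior(post, f, value = 1, sigma_n2 = 1)
  expect_equal(up$mean[5], 0.5)
  expect_equal(up$cov[5, 5], 0.5)
  expect_equal(up$mean[-5], rep(0, 80))
  expect_error(update_posterior(post, f[1:10], 1), "length")
})

test_that("sequential updates equal the one-shot closed-form posterior", {
  # independent oracle: direct matrix solution of Bayesian linear regression
  set.seed(42)
  for (rep in 1:5) {
    d <- sample(3:10, 1)
    n <- sample(10:50, 1)
    sn2 <- runif(1, 0.5, 2)
    mu0 <- rnorm(d, 0, 0.5)
    v0 <- runif(d, 0.2, 2)
    X <- matrix(rnorm(n * d), n, d)
    y <- rnorm(n, X %*% rnorm(d), 1)
    S0inv <- diag(1 / v0)
    Sn <- solve(S0inv + crossprod(X) / sn2)
    mun <- drop(Sn %*% (S0inv %*% mu0 + crossprod(X, y) / sn2))
    post <- structure(list(mean = mu0, cov = diag(v0)),
                      class = "lvoc_posterior")
    for (i in seq_len(n)) {
      post <- update_posterior(post, X[i, ], y[i], sn2)
    }
    expect_equal(post$mean, mun, tolerance = 1e-8)
    expect_equal(post$cov, Sn, tolerance = 1e-8)
  }
})

test_that("posterior with zero observations equals the prior", {
  p <- lvoc_prior(-0.17, 0.11, global_precision_multiplier = 10)
  expect_equal(p$mean, rep(-0.17, 81))
  expect_equal(diag(p$cov), c(rep(0.11, 80), 0.011))
  expect_true(all(p$cov[upper.tri(p$cov)] == 0))
})

test_that("Thompson sampling picks endpoint control in degenerate limits", {
  params <- lvoc_params()
  stim <- list(color = "red", word = "blue")
  # essentially point mass at all-zero weights: value = -cost, decreasing
  flat <- structure(list(mean = rep(0, 81), cov = diag(1e-18, 81)),
                    class = "lvoc_posterior")
  expect_equal(thompson_choose(stim, flat, 0, params), 0)
  # large positive global weight: net value increasing in c
  pos <- flat
  pos$mean[81] <- 50
  expect_equal(thompson_choose(stim, pos, 0, params), 1)
})

test_that("Thompson choice frequencies match brute-force sampling", {
  set.seed(7)
  params <- lvoc_params(c_grid = c(0, 1))
  post <- lvoc_prior(mu_prior = 0.05, tau_prior = 0.04)
  stim <- list(color = "green", word = "pink")
  n <- 4000
  chosen <- replicate(n, thompson_choose(stim, post, 0, params))
  p_hat <- mean(chosen == 1)
  # brute force: P(choose 1) = P(sum of 4 active weights > cost(1)-cost(0))
  gap <- control_cost(1, 0) - control_cost(0, 0)
  draws <- rnorm(2e5, 4 * 0.05, sqrt(4 * 0.04))
  p_ref <- mean(draws > gap)
  expect_lt(abs(p_hat - p_ref), 4 * sqrt(p_ref * (1 - p_ref) / n))
})

test_that("agent limits: pinned drift earns everything, no control earns none", {
  sched <- generate_experiment(1, group = 20, seed = 5)
  cn_only <- sched
  cn_only$rewarded_task <- "CN"
  # weights pinned high, huge controlled drift: almost every trial rewarded
  strong <- lvoc_params(mu_prior = 20, tau_prior = 1e-4, d_controlled = 30,
                        d_automatic = 1)
  beh <- run_lvoc_agent(cn_only, strong, seed = 1)
  expect_gt(mean(beh$rewarded), 0.99)
  # control never engaged on CN-rewarded trials with a strong automatic
  # pathway: reward approximately zero
  lazy <- lvoc_params(mu_prior = -50, tau_prior = 1e-4, d_automatic = 30)
  beh0 <- run_lvoc_agent(cn_only, lazy, seed = 2)
  expect_equal(unique(beh0$c_chosen), 0)
  expect_lt(mean(beh0$rewarded), 0.01)
})

test_that("a full 520-trial run is reproducible under a fixed seed", {
  sched <- generate_experiment(1, group = 50, seed = 9)
  b1 <- run_lvoc_agent(sched, lvoc_params(), seed = 33)
  b2 <- run_lvoc_agent(sched, lvoc_params(), seed = 33)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 520)
  expect_true(all(b1$rt[!b1$timed_out] >= lvoc_params()$t0))
  expect_true(all(b1$rt[b1$timed_out] == lvoc_params()$deadline))
  expect_true(all(b1$c_chosen >= 0 & b1$c_chosen <= 1))
})
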