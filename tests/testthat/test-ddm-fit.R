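test_that("maximum-likelihood fit recovers generating diffusion parameters", {
  p <- ddm_params(v = 1.5, a = 1.8, t0 = 0.3, deadline = 10)
  dat <- ddm_fixture(p, 2000, seed = 9)
  fit <- ddm_fit_mle(dat)
  expect_lt(abs(unname(fit$drift) - 1.5), 0.15)
  expect_lt(abs(fit$a - 1.8), 0.1)
  expect_lt(abs(fit$t0 - 0.3), 0.05)
  expect_equal(fit$convergence, 0)
})

test_that("drift estimates are unbiased at the null", {
  dat <- ddm_fixture(ddm_params(v = 0, a = 2, t0 = 0.3, deadline = 20),
                     2000, seed = 21)
  fit <- ddm_fit_mle(dat)
  # 3 x approximate SE of a null drift estimate at this n
  expect_lt(abs(unname(fit$drift)), 3 * 0.06)
})

test_that("flipping the response coding flips the fitted drift sign", {
  dat <- ddm_fixture(ddm_params(v = 1, a = 1.6, t0 = 0.3, deadline = 10),
                     1200, seed = 5)
  flipped <- dat
  flipped$response_task <- ifelse(dat$response_task == "CN", "WR", "CN")
  f1 <- ddm_fit_mle(dat)
  f2 <- ddm_fit_mle(flipped)
  expect_equal(unname(f1$drift), -unname(f2$drift), tolerance = 1e-3)
})

test_that("fit requires enough trials per condition and flags degeneracy", {
  dat <- ddm_fixture(ddm_params(v = 1, a = 1.6, deadline = 10), 30, seed = 2)
  expect_error(ddm_fit_mle(dat, min_per_condition = 50), "fewer than")
  all_up <- ddm_fixture(ddm_params(v = 30, a = 1.6, deadline = 10),
                        60, seed = 3)
  expect_warning(ddm_fit_mle(all_up, min_per_condition = 20), "degenerate")
})

test_that("Bayesian fit agrees with the MLE and is seed-reproducible", {
  p <- ddm_params(v = 1.5, a = 1.8, t0 = 0.3, deadline = 10)
  dat <- ddm_fixture(p, 800, seed = 13)
  mle <- ddm_fit_mle(dat)
  bf <- ddm_fit_bayes(dat, n_samples = 4000, burn_in = 2000, seed = 4)
  expect_true(bf$converged)
  # posterior mean of drift within 2 posterior SDs of the generating value
  expect_lt(abs(bf$mean[["X"]] - 1.5), 2 * sd(bf$samples[, "X"]))
  # and close to the MLE relative to the posterior spread
  expect_lt(abs(bf$mean[["X"]] - unname(mle$drift)), sd(bf$samples[, "X"]))
  expect_lt(abs(bf$mean[["a"]] - mle$a), sd(bf$samples[, "a"]))
  bf2 <- ddm_fit_bayes(dat, n_samples = 4000, burn_in = 2000, seed = 4)
  expect_identical(bf$samples, bf2$samples)
  expect_equal(nrow(bf$samples), 2000)
})

test_that("highest density interval is the narrowest covering interval", {
  set.seed(1)
  x <- c(rnorm(4000), rnorm(1000, 6))
  h <- hdi(x, 0.5)
  # half the mass sits in the tight main mode, far from the outlier mode
  expect_true(h[1] > -2 && h[2] < 2)
  expect_equal(hdi(c(3, 3, 3, 3), 0.95), c(3, 3))
})

test_that("posterior difference classification follows its HDI", {
  x <- rnorm(5000)
  same <- posterior_difference_hdi(x, x)
  expect_equal(same$interval, c(0, 0))
  expect_equal(same$classification, "contains zero")
  set.seed(2)
  a <- rnorm(5000, 1)
  b <- rnorm(5000, 0)
  pd <- posterior_difference_hdi(a, b)
  # analytic difference distribution N(1, 2): central 95% interval
  expect_equal(pd$interval[1], 1 - 1.96 * sqrt(2), tolerance = 0.15)
  expect_equal(pd$interval[2], 1 + 1.96 * sqrt(2), tolerance = 0.15)
  shift <- posterior_difference_hdi(b + 10, b)
  expect_equal(shift$classification, "strictly positive")
  expect_equal(shift$interval, c(10, 10))
  expect_error(posterior_difference_hdi(a, b[1:10]), "equal length")
})

test_that("group-pair difference table classifies parameter changes", {
  set.seed(3)
  mk <- function(v) {
    structure(list(samples = cbind(BOTH = rnorm(2000, v, 0.1),
                                   a = rnorm(2000, 1.5, 0.1))),
              class = "ddm_bayes_fit")
  }
  tab <- posterior_difference_table(list(`0` = mk(0), `20` = mk(-1),
                                         `50` = mk(-2)))
  expect_equal(nrow(tab), 4)
  both <- tab[tab$parameter == "BOTH", ]
  expect_true(all(both$classification == "strictly positive"))
  a <- tab[tab$parameter == "a", ]
  expect_true(all(a$classification == "contains zero"))
})
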