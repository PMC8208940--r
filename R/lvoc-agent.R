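#' Control cost parameters
#'
#' The cost of allocating control comprises an opportunity (response-time)
#' cost `omega * RT` in points, an implementation cost
#' `exp(alpha + beta * |c_t|)`, and a reconfiguration cost
#' `exp(alpha + beta * |c_t - c_prev|)` that penalizes diverging from the
#' previous control signal. With `baseline_subtracted = TRUE` the constant
#' `2 * exp(alpha)` is removed so that the cost of allocating no control
#' (and not having just reduced it) is exactly zero.
#'
#' @param alpha implementation-cost offset (default -1).
#' @param beta implementation-cost slope (default 1/4).
#' @param omega opportunity cost in points per second (default 0.44,
#'   the task's points-per-second equivalent of roughly an $8/hour wage).
#' @param baseline_subtracted subtract `2 * exp(alpha)` so `cost(0, 0) = 0`.
#' @return an object of class `cost_params`.
#' @export
cost_params <- function(alpha = -1, beta = 1 / 4, omega = 0.44,
                        baseline_subtracted = FALSE) {
  stopifnot(omega >= 0)
  structure(list(alpha = alpha, beta = beta, omega = omega,
                 baseline_subtracted = baseline_subtracted),
            class = "cost_params")
}

#' Deterministic control cost of a control signal
#'
#' Implementation plus reconfiguration cost (the prospective components of
#' the control cost, known at choice time; the opportunity cost depends on
#' the realized response time and is accounted for in
#' [experienced_value()]).
#'
#' @param c_t chosen control signal(s) in \[0, 1\].
#' @param c_prev previous trial's control signal.
#' @param params a [cost_params()] object.
#' @return cost in points (vectorized over `c_t`).
#' @examples
#' control_cost(0, 0)  # 2 * exp(-1)
#' control_cost(0, 0, cost_params(baseline_subtracted = TRUE))  # 0
#' @export
control_cost <- function(c_t, c_prev = 0, params = cost_params()) {
  stopifnot(inherits(params, "cost_params"))
  cost <- exp(params$alpha + params$beta * abs(c_t)) +
    exp(params$alpha + params$beta * abs(c_t - c_prev))
  if (params$baseline_subtracted) cost <- cost - 2 * exp(params$alpha)
  cost
}

#' Experienced value of a control allocation
#'
#' The realized learning target: reward earned minus the opportunity cost of
#' the time spent responding, `R - omega * rt`. The deterministic
#' implementation/reconfiguration costs are handled at choice time by
#' default (see the package vignette for the cost-accounting variants).
#'
#' @param reward points earned.
#' @param rt response time in seconds (>= 0).
#' @param params a [cost_params()] object.
#' @return experienced value in points.
#' @export
experienced_value <- function(reward, rt, params = cost_params()) {
  stopifnot(all(rt >= 0))
  reward - params$omega * rt
}

# ---- feature basis -------------------------------------------------------

.n_features <- 81L  # 8 colors + 8 words + 64 conjunctions + 1 global

.feature_names <- function() {
  conj <- outer(.lvoc_labels, .lvoc_labels,
                function(a, b) paste0("conj_", a, "_", b))
  c(paste0("color_", .lvoc_labels), paste0("word_", .lvoc_labels),
    as.vector(t(conj)), "global")
}

.active_indices <- function(color, word, include_conjunctions = TRUE) {
  ci <- .label_index(color)
  wi <- .label_index(word)
  idx <- c(ci, 8L + wi)
  if (include_conjunctions) idx <- c(idx, 16L + 8L * (ci - 1L) + wi)
  c(idx, .n_features)
}

#' Featurize a stimulus at a control intensity
#'
#' The LVOC feature basis contains one indicator per color, one per word,
#' one per color-by-word conjunction, and one global control feature. Each
#' feature takes the value of the control signal `c` if the stimulus has its
#' preferred property (the global feature is always active), and 0 otherwise,
#' so a stimulus activates exactly four features (three with conjunctions
#' disabled), all equal to `c`.
#'
#' @param color,word stimulus labels (one of the eight task labels each).
#' @param c control signal intensity in \[0, 1\].
#' @param include_conjunctions include the conjunction features (default
#'   TRUE; disabling them makes the basis strictly linear in the individual
#'   features and hence unable to represent XOR contingencies).
#' @return named numeric vector of length 81.
#' @export
lvoc_features <- function(color, word, c, include_conjunctions = TRUE) {
  stopifnot(length(color) == 1, length(word) == 1, c >= 0, c <= 1)
  f <- numeric(.n_features)
  names(f) <- .feature_names()
  f[.active_indices(color, word, include_conjunctions)] <- c
  f
}

# ---- Bayesian linear regression over feature weights ---------------------

#' Prior over LVOC feature weights
#'
#' Each weight has an independent normal prior `N(mu_prior, tau_prior)`
#' (variance parameterization), shared across features. The global control
#' feature's prior variance can be shrunk by `global_precision_multiplier`
#' (> 1 increases its prior precision, letting the stimulus-independent
#' value of control be learned faster than feature-specific values).
#'
#' @param mu_prior prior mean of every weight.
#' @param tau_prior prior variance of every weight (> 0).
#' @param global_precision_multiplier factor (>= 1) dividing the global
#'   feature's prior variance.
#' @param n_features basis dimension (default 81).
#' @return an object of class `lvoc_posterior` with elements `mean`
#'   (numeric vector) and `cov` (covariance matrix).
#' @export
lvoc_prior <- function(mu_prior = -0.17, tau_prior = 0.11,
                       global_precision_multiplier = 1,
                       n_features = .n_features) {
  stopifnot(tau_prior > 0, global_precision_multiplier >= 1)
  v <- rep(tau_prior, n_features)
  v[n_features] <- tau_prior / global_precision_multiplier
  structure(list(mean = rep(mu_prior, n_features), cov = diag(v)),
            class = "lvoc_posterior")
}

#' @export
print.lvoc_posterior <- function(x, ...) {
  cat(sprintf("LVOC weight posterior over %d features\n", length(x$mean)))
  cat(sprintf("  mean range: [%.3f, %.3f]; trace(cov) = %.3f\n",
              min(x$mean), max(x$mean), sum(diag(x$cov))))
  invisible(x)
}

#' Conjugate update of the weight posterior from one observation
#'
#' Normal linear-regression update with known observation-noise variance:
#' the experienced value `value` is regressed onto the feature vector.
#' Sequential single-observation updates reproduce the one-shot closed-form
#' posterior for a whole design matrix.
#'
#' @param posterior an [lvoc_prior()] / previously updated posterior.
#' @param features numeric feature vector, same length as the posterior mean.
#' @param value observed experienced value (scalar).
#' @param sigma_n2 observation-noise variance (default 1).
#' @return the updated `lvoc_posterior`.
#' @export
update_posterior <- function(posterior, features, value, sigma_n2 = 1) {
  stopifnot(inherits(posterior, "lvoc_posterior"),
            length(features) == length(posterior$mean),
            length(value) == 1, sigma_n2 > 0)
  k <- drop(posterior$cov %*% features)
  denom <- sigma_n2 + sum(features * k)
  resid <- value - sum(features * posterior$mean)
  posterior$mean <- posterior$mean + k * resid / denom
  posterior$cov <- posterior$cov - tcrossprod(k) / denom
  posterior
}

#' Agent configuration for LVOC simulations
#'
#' Bundles the learning, cost, and diffusion settings of the LVOC agent.
#' Defaults are the best-fitting parameters of the model when fit to the
#' condition-level drift rates of the behavioral study
#' (`d_controlled = 1.32`, `d_automatic = 3.22`, `mu_prior = -0.17`,
#' `tau_prior = 0.11`).
#'
#' @param mu_prior,tau_prior prior mean and variance of the feature weights.
#' @param d_controlled,d_automatic drift magnitudes of the controlled
#'   (color-naming) and automatic (word-reading) pathways.
#' @param sigma_n2 observation-noise variance of the Bayesian regression.
#' @param cost a [cost_params()] object.
#' @param c_grid candidate control intensities (must include 0 and 1).
#' @param global_precision_multiplier prior-precision multiplier for the
#'   global control feature (1 = base model; > 1 = global-bias variant).
#' @param include_conjunctions include conjunction features in the basis.
#' @param cost_in_target subtract the deterministic implementation and
#'   reconfiguration costs from the learning target as well (default TRUE,
#'   the model's stated learning target `R - cost(s, c)`); `FALSE` accounts
#'   for those components at choice time only, a variant that avoids
#'   counting them on both sides of the value comparison.
#' @param threshold,noise,t0,dt,deadline diffusion settings (boundary
#'   separation, within-trial noise, non-decision time, Euler step,
#'   response deadline).
#' @return an object of class `lvoc_params`.
#' @export
lvoc_params <- function(mu_prior = -0.17, tau_prior = 0.11,
                        d_controlled = 1.32, d_automatic = 3.22,
                        sigma_n2 = 1, cost = cost_params(),
                        c_grid = seq(0, 1, by = 0.05),
                        global_precision_multiplier = 1,
                        include_conjunctions = TRUE,
                        cost_in_target = TRUE,
                        threshold = 2, noise = 1, t0 = 0.3,
                        dt = 0.001, deadline = 3) {
  stopifnot(tau_prior > 0, d_controlled > 0, d_automatic > 0, sigma_n2 > 0,
            threshold > 0, noise > 0, dt > 0,
            any(c_grid == 0), any(c_grid == 1),
            all(c_grid >= 0 & c_grid <= 1))
  structure(list(
    mu_prior = mu_prior, tau_prior = tau_prior,
    d_controlled = d_controlled, d_automatic = d_automatic,
    sigma_n2 = sigma_n2, cost = cost, c_grid = sort(c_grid),
    global_precision_multiplier = global_precision_multiplier,
    include_conjunctions = include_conjunctions,
    cost_in_target = cost_in_target,
    threshold = threshold, noise = noise, t0 = t0, dt = dt,
    deadline = deadline
  ), class = "lvoc_params")
}

#' @export
print.lvoc_params <- function(x, ...) {
  cat("LVOC agent configuration\n")
  cat(sprintf("  prior: N(%.3f, %.3f); sigma_n2 = %.2f%s\n",
              x$mu_prior, x$tau_prior, x$sigma_n2,
              if (x$global_precision_multiplier > 1)
                sprintf("; global precision x%.0f",
                        x$global_precision_multiplier) else ""))
  cat(sprintf("  drift: d_controlled = %.2f, d_automatic = %.2f\n",
              x$d_controlled, x$d_automatic))
  cat(sprintf("  DDM: a = %.2f, s = %.2f, t0 = %.2f, deadline = %.1f s\n",
              x$threshold, x$noise, x$t0, x$deadline))
  invisible(x)
}

#' Thompson-sampled control signal for one stimulus
#'
#' Draws one full weight vector from the posterior and returns the grid
#' value of `c` maximizing the sampled value of control
#' `sum_i w_i f_i(s, c) - cost(c, c_prev)`; exact ties break toward the
#' smaller (less effortful) `c`.
#'
#' @param stimulus list with elements `color` and `word`.
#' @param posterior an `lvoc_posterior`.
#' @param c_prev previous control signal.
#' @param params an [lvoc_params()] object.
#' @return the chosen control intensity.
#' @export
thompson_choose <- function(stimulus, posterior, c_prev = 0,
                            params = lvoc_params()) {
  stopifnot(inherits(posterior, "lvoc_posterior"))
  idx <- .active_indices(stimulus$color, stimulus$word,
                         params$include_conjunctions)
  S <- posterior$cov[idx, idx, drop = FALSE]
  L <- tryCatch(t(chol(S)), error = function(e) {
    t(chol(S + diag(1e-10, nrow(S))))
  })
  wtil <- posterior$mean[idx] + drop(L %*% rnorm(length(idx)))
  W <- sum(wtil)
  vals <- params$c_grid * W - control_cost(params$c_grid, c_prev, params$cost)
  params$c_grid[which.max(vals)]
}

# ---- full agent runs -----------------------------------------------------

#' Run the LVOC agent over an experiment schedule
#'
#' For every trial: choose a control intensity by Thompson sampling, map it
#' to a drift rate, simulate the diffusion to obtain a response and response
#' time, score the reward, and update the weight posterior with the
#' experienced value at the chosen control's features. The agent state
#' (posterior and previous control signal) carries across trials within a
#' participant and resets between participants.
#'
#' @param schedule an experiment schedule from [generate_experiment()]
#'   (one or more participants).
#' @param params an [lvoc_params()] object.
#' @param seed optional integer seed.
#' @return the schedule with behavioral columns appended: `c_chosen`,
#'   `drift` (toward the CN/upper boundary), `response_task`
#'   (`"CN"`, `"WR"`, or `"timeout"`), `rt`, `timed_out`, `points_earned`,
#'   `rewarded`.
#' @export
run_lvoc_agent <- function(schedule, params = lvoc_params(), seed = NULL) {
  stopifnot(inherits(params, "lvoc_params"))
  if (!is.null(seed)) set.seed(seed)
  prior <- lvoc_prior(params$mu_prior, params$tau_prior,
                      params$global_precision_multiplier)
  pieces <- lapply(split(schedule, schedule$participant), function(sub) {
    sub <- sub[order(sub$trial_index), , drop = FALSE]
    res <- cpp_run_lvoc(
      .label_index(sub$color), .label_index(sub$word),
      as.integer(sub$rewarded_task == "CN"), as.integer(sub$points),
      prior$mean, prior$cov, params$sigma_n2,
      params$cost$alpha, params$cost$beta, params$cost$omega,
      params$cost$baseline_subtracted, params$cost_in_target,
      params$c_grid, params$d_controlled, params$d_automatic,
      params$threshold, params$threshold / 2, params$noise, params$t0,
      params$dt, params$deadline,
      params$include_conjunctions, 0.0
    )
    sub$c_chosen <- res$c_chosen
    sub$drift <- res$drift
    sub$response_task <- c("timeout", "WR", "CN")[res$response + 2L]
    sub$rt <- res$rt
    sub$timed_out <- res$timed_out
    sub$points_earned <- res$reward
    sub$rewarded <- res$reward > 0
    sub
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Simulate a multi-group LVOC cohort
#'
#' Generates schedules and runs the LVOC agent for `n_per_group`
#' participants in each EITHER-frequency group, with per-participant
#' diffusion threshold and noise drawn from group-level normal
#' distributions (truncated away from zero), emulating individual
#' differences.
#'
#' @param n_per_group participants per group.
#' @param groups EITHER percentages to simulate (default `c(0, 20, 50)`).
#' @param params an [lvoc_params()] object (its `threshold`/`noise` are
#'   overridden by the per-participant draws).
#' @param seed integer seed.
#' @param threshold_mean,threshold_sd normal distribution of per-participant
#'   boundary separation.
#' @param noise_mean,noise_sd normal distribution of per-participant
#'   within-trial noise.
#' @param mapping optional shared [build_feature_mapping()].
#' @return a behavioral data.frame as from [run_lvoc_agent()], participants
#'   numbered consecutively across groups.
#' @export
simulate_lvoc_cohort <- function(n_per_group = 10, groups = c(0, 20, 50),
                                 params = lvoc_params(), seed = 1,
                                 threshold_mean = 2, threshold_sd = 0.3,
                                 noise_mean = 1, noise_sd = 0.1,
                                 mapping = NULL) {
  set.seed(seed)
  if (is.null(mapping)) mapping <- build_feature_mapping()
  pid <- 0L
  out <- list()
  for (g in groups) {
    sched <- generate_experiment(n_per_group, group = g,
                                 seed = sample.int(.Machine$integer.max, 1),
                                 mapping = mapping)
    sched$participant <- sched$participant + pid
    for (p in unique(sched$participant)) {
      pp <- params
      pp$threshold <- max(0.5, rnorm(1, threshold_mean, threshold_sd))
      pp$noise <- max(0.2, rnorm(1, noise_mean, noise_sd))
      out[[length(out) + 1L]] <-
        run_lvoc_agent(sched[sched$participant == p, , drop = FALSE], pp)
    }
    pid <- pid + n_per_group
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
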