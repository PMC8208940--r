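#' Specification of the simulation-based likelihood
#'
#' Controls how the experiment is simulated when evaluating candidate LVOC
#' parameters: how many times the whole experiment is repeated per
#' candidate, how many participants per group, and the group-level
#' distributions from which each simulated participant's diffusion
#' threshold and noise are drawn (typically taken from a condition-level
#' diffusion fit).
#'
#' @param n_simulations experiment repetitions per candidate (>= 2).
#' @param n_per_group simulated participants per EITHER-frequency group
#'   (>= 1; the default 10 per group gives the study's 30-participant
#'   cohort).
#' @param groups EITHER percentages.
#' @param cohort_size number of participants whose average drift the
#'   likelihood describes (divides the simulated variance; default 30).
#' @param threshold_mean,threshold_sd,noise_mean,noise_sd sampling
#'   distributions of per-participant threshold and noise.
#' @return a list of class `sim_spec`.
#' @export
sim_spec <- function(n_simulations = 100, n_per_group = 10,
                     groups = c(0, 20, 50), cohort_size = 30,
                     threshold_mean = 2, threshold_sd = 0.3,
                     noise_mean = 1, noise_sd = 0.1) {
  stopifnot(n_simulations >= 2, n_per_group >= 1, cohort_size >= 2)
  structure(list(n_simulations = n_simulations, n_per_group = n_per_group,
                 groups = groups, cohort_size = cohort_size,
                 threshold_mean = threshold_mean, threshold_sd = threshold_sd,
                 noise_mean = noise_mean, noise_sd = noise_sd),
            class = "sim_spec")
}

#' Per-participant mean drift toward the goal-consistent response
#'
#' Summarizes simulated (or real, if drift were observed) trial-level drift
#' rates: transfer-phase drift is re-signed toward the goal-consistent
#' response of each trial and averaged within trial type per participant.
#' EITHER-COLOR and EITHER-WORD trials are pooled as EITHER.
#'
#' @param behavior a behavioral data.frame containing a `drift` column
#'   (drift toward the CN boundary, as produced by [run_lvoc_agent()]).
#' @return data.frame with `participant`, `group`, `trial_type`,
#'   `mean_drift`.
#' @export
participant_drift_means <- function(behavior) {
  tr <- behavior[behavior$phase == "transfer", , drop = FALSE]
  stopifnot("drift" %in% names(tr), nrow(tr) > 0)
  tr$goal_drift <- ifelse(tr$rewarded_task == "CN", tr$drift, -tr$drift)
  tr$trial_type[tr$trial_type %in% c("EITHER_COLOR", "EITHER_WORD")] <-
    "EITHER"
  agg <- aggregate(list(mean_drift = tr$goal_drift),
                   tr[, c("participant", "group", "trial_type")], mean)
  agg[order(agg$group, agg$trial_type, agg$participant), ]
}

#' Simulate cohort-level drift summaries under candidate LVOC parameters
#'
#' Repeats the full three-group experiment `n_simulations` times. Each
#' simulated participant runs all 520 trials with threshold and noise drawn
#' from the specified group-level distributions; trial-level drift rates
#' are averaged within trial type per participant, and the mean and
#' variance of those per-participant means are returned per trial type and
#' group (pooled across simulations).
#'
#' @param params an [lvoc_params()] object (the candidate).
#' @param spec a [sim_spec()].
#' @param seed integer seed (fixing it makes the summary deterministic).
#' @return data.frame with `group`, `trial_type`, `mean_drift`,
#'   `var_drift`, `n_participants`.
#' @export
simulate_cohort_drift <- function(params = lvoc_params(), spec = sim_spec(),
                                  seed = 1) {
  set.seed(seed)
  per <- list()
  for (r in seq_len(spec$n_simulations)) {
    beh <- simulate_lvoc_cohort(
      n_per_group = spec$n_per_group, groups = spec$groups, params = params,
      seed = sample.int(.Machine$integer.max, 1),
      threshold_mean = spec$threshold_mean, threshold_sd = spec$threshold_sd,
      noise_mean = spec$noise_mean, noise_sd = spec$noise_sd
    )
    pm <- participant_drift_means(beh)
    pm$participant <- paste0(r, ":", pm$participant)
    per[[r]] <- pm
  }
  all <- do.call(rbind, per)
  agg <- aggregate(list(mean_drift = all$mean_drift),
                   all[, c("group", "trial_type")], mean)
  v <- aggregate(list(var_drift = all$mean_drift),
                 all[, c("group", "trial_type")], var)
  n <- aggregate(list(n_participants = all$mean_drift),
                 all[, c("group", "trial_type")], length)
  out <- merge(merge(agg, v), n)
  out[order(out$group, out$trial_type), ]
}

#' Simulation-based log-likelihood of observed drift means
#'
#' The likelihood of the observed condition-level drift means is a product
#' of normal densities: for each trial type by group cell, the observed
#' mean is scored against the simulated mean with variance equal to the
#' simulated between-participant variance divided by the cohort size.
#'
#' @param observed data.frame with `group`, `trial_type`, `mean_drift`
#'   (the data being fit).
#' @param simulated data.frame from [simulate_cohort_drift()].
#' @param cohort_size divisor of the simulated variance (default 30).
#' @param variance_floor smallest admissible sampling variance; degenerate
#'   (zero-variance) simulated cells are floored to it.
#' @param warn_zero_variance warn when the floor is applied (default TRUE;
#'   the optimizer disables the warning to avoid flooding).
#' @return log-likelihood (scalar).
#' @export
sim_likelihood <- function(observed, simulated, cohort_size = 30,
                           variance_floor = 1e-8,
                           warn_zero_variance = TRUE) {
  m <- merge(observed, simulated, by = c("group", "trial_type"),
             suffixes = c("_obs", "_sim"))
  if (nrow(m) < nrow(observed)) {
    stop("simulated summary lacks some observed conditions")
  }
  v <- m$var_drift / cohort_size
  if (any(v <= variance_floor)) {
    if (warn_zero_variance) warning("zero simulated variance floored")
    v <- pmax(v, variance_floor)
  }
  sum(dnorm(m$mean_drift_obs, m$mean_drift_sim, sqrt(v), log = TRUE))
}

# map (0,1) -> box and back, for bounded Nelder-Mead
.to_box <- function(u, lower, upper) lower + (upper - lower) / (1 + exp(-u))
.from_box <- function(x, lower, upper) {
  p <- pmin(pmax((x - lower) / (upper - lower), 1e-6), 1 - 1e-6)
  log(p / (1 - p))
}

#' Fit LVOC parameters to condition-level drift means
#'
#' Maximizes the simulation-based likelihood over the prior mean and
#' variance of the feature weights and the controlled/automatic drift
#' magnitudes, using a bounded derivative-free simplex search. Common
#' random numbers (the same simulation seed for every candidate) make the
#' objective deterministic given `seed`, so the search is reproducible and
#' its comparisons are not dominated by simulation noise.
#'
#' @param observed data.frame with `group`, `trial_type`, `mean_drift`.
#' @param spec a [sim_spec()].
#' @param start named start values (`mu_prior`, `tau_prior`,
#'   `d_controlled`, `d_automatic`).
#' @param lower,upper named bounds of the search box.
#' @param seed integer seed (also the common-random-numbers seed).
#' @param base_params an [lvoc_params()] carrying all non-fitted settings
#'   (cost function, grid, variant flags).
#' @param maxit maximum objective evaluations for the simplex search.
#' @return list of class `lvoc_fit`: `params` (fitted [lvoc_params()]),
#'   `estimates`, `logLik`, `trace` (data.frame of evaluated candidates),
#'   `convergence`.
#' @export
fit_lvoc <- function(observed, spec = sim_spec(),
                     start = c(mu_prior = 0, tau_prior = 0.2,
                               d_controlled = 1.5, d_automatic = 3),
                     lower = c(mu_prior = -1, tau_prior = 0.01,
                               d_controlled = 0.2, d_automatic = 0.5),
                     upper = c(mu_prior = 1, tau_prior = 1,
                               d_controlled = 4, d_automatic = 6),
                     seed = 1, base_params = lvoc_params(), maxit = 60) {
  nm <- c("mu_prior", "tau_prior", "d_controlled", "d_automatic")
  stopifnot(all(nm %in% names(start)), all(nm %in% names(lower)),
            all(nm %in% names(upper)))
  trace <- list()
  objective <- function(u) {
    x <- .to_box(u, lower[nm], upper[nm])
    p <- base_params
    p$mu_prior <- x[["mu_prior"]]
    p$tau_prior <- x[["tau_prior"]]
    p$d_controlled <- x[["d_controlled"]]
    p$d_automatic <- x[["d_automatic"]]
    sim <- simulate_cohort_drift(p, spec, seed = seed)  # common random numbers
    ll <- sim_likelihood(observed, sim, spec$cohort_size,
                         warn_zero_variance = FALSE)
    trace[[length(trace) + 1L]] <<- c(x, logLik = ll)
    -ll
  }
  u0 <- .from_box(start[nm], lower[nm], upper[nm])
  opt <- optim(u0, objective, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-4))
  if (opt$convergence != 0) {
    warning("simplex search stopped before convergence; ",
            "best candidate so far returned")
  }
  est <- .to_box(opt$par, lower[nm], upper[nm])
  names(est) <- nm
  p <- base_params
  p$mu_prior <- est[["mu_prior"]]
  p$tau_prior <- est[["tau_prior"]]
  p$d_controlled <- est[["d_controlled"]]
  p$d_automatic <- est[["d_automatic"]]
  structure(list(params = p, estimates = est, logLik = -opt$value,
                 trace = as.data.frame(do.call(rbind, trace)),
                 convergence = opt$convergence),
            class = "lvoc_fit")
}

#' @export
print.lvoc_fit <- function(x, ...) {
  cat(sprintf("LVOC fit (simulation-based likelihood): logLik = %.2f\n",
              x$logLik))
  print(round(x$estimates, 4))
  invisible(x)
}
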