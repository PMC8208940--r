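# Vectorized first-passage density at the lower boundary of a unit
# diffusion on [0, 1] started at w, at normalized times u.
.wfpt_f0_vec <- function(u, w, err = 1e-10) {
  out <- numeric(length(u))
  pos <- which(u > 0)
  if (!length(pos)) return(out)
  uu <- u[pos]
  kl <- ifelse(2 * pi * uu * err < 1,
               pmax(sqrt(-2 * log(pi * uu * err) / (pi^2 * uu)),
                    1 / (pi * sqrt(uu))),
               1 / (pi * sqrt(uu)))
  ks <- ifelse(2 * sqrt(2 * pi * uu) * err < 1,
               pmax(2 + sqrt(-2 * uu * log(2 * sqrt(2 * pi * uu) * err)),
                    sqrt(uu) + 1),
               2)
  small <- ks < kl
  res <- numeric(length(uu))
  if (any(small)) {
    us <- uu[small]
    K <- max(ceiling(ks[small]))
    k <- seq(-floor((K - 1) / 2), ceiling((K - 1) / 2))
    wk <- outer(rep(w, length(us)), 2 * k, "+")
    res[small] <- rowSums(wk * exp(-wk^2 / (2 * us))) / sqrt(2 * pi * us^3)
  }
  if (any(!small)) {
    ul <- uu[!small]
    K <- max(ceiling(kl[!small]))
    k <- seq_len(K)
    mat <- exp(-outer(ul, k^2 * pi^2 / 2)) *
      matrix(k * sin(k * pi * w), nrow = length(ul), ncol = K, byrow = TRUE)
    res[!small] <- pi * rowSums(mat)
  }
  out[pos] <- res
  out
}

# Defective first-passage density at either boundary; vectorized over rt.
.wfpt_pdf <- function(rt, v, a, w, t0, s = 1, upper = FALSE) {
  v <- v / s
  a <- a / s
  if (upper) {
    v <- -v
    w <- 1 - w
  }
  tau <- rt - t0
  out <- numeric(length(rt))
  ok <- which(tau > 0)
  if (length(ok)) {
    u <- tau[ok] / a^2
    out[ok] <- exp(-v * a * w - v^2 * tau[ok] / 2) / a^2 * .wfpt_f0_vec(u, w)
  }
  out
}

# Negative log-likelihood of condition-coded diffusion data.
# cond: integer condition index per trial (drift per condition);
# upper: logical, TRUE when the trial absorbed at the upper
# (goal-consistent) boundary.
.ddm_negll <- function(rt, upper, cond, v, a, t0, w = 0.5, s = 1) {
  if (a <= 0 || t0 < 0 || t0 >= min(rt) || w <= 0 || w >= 1) return(1e10)
  ll <- 0
  for (k in seq_along(v)) {
    for (up in c(TRUE, FALSE)) {
      sel <- cond == k & upper == up
      if (!any(sel)) next
      d <- .wfpt_pdf(rt[sel], v[k], a, w, t0, s, upper = up)
      if (any(d <= 0) || any(!is.finite(d))) return(1e10)
      ll <- ll + sum(log(d))
    }
  }
  -ll
}

.ddm_prepare <- function(data, drift_by) {
  stopifnot(all(c("rt", "response_task", "rewarded_task") %in% names(data)))
  bad <- !data$response_task %in% c("CN", "WR")
  if (any(bad)) {
    stop("data contain non-task responses; run apply_filters() first")
  }
  cond_f <- interaction(data[, drift_by, drop = FALSE], drop = TRUE,
                        lex.order = TRUE, sep = ":")
  list(rt = data$rt,
       upper = data$response_task == data$rewarded_task,
       cond = as.integer(cond_f),
       levels = levels(cond_f))
}

#' Maximum-likelihood condition-level diffusion fit
#'
#' Fits one drift rate per condition cell (default: per trial type) plus a
#' shared boundary separation and non-decision time, by maximizing the
#' summed log Wiener first-passage density over trials. Drift is
#' parameterized toward the goal-consistent response: the upper boundary is
#' the response matching the rewarded task. Starting point is fixed at the
#' midpoint and the noise at 1 (scaling convention).
#'
#' @param data filtered behavioral data.frame (columns `rt`,
#'   `response_task`, `rewarded_task`, plus the `drift_by` columns).
#' @param drift_by character vector of columns defining drift conditions.
#' @param min_per_condition minimum trials required per condition cell.
#' @return an object of class `ddm_fit`: list with `drift` (named vector of
#'   per-condition drift rates), `a`, `t0`, `logLik`, `n`, `convergence`.
#' @export
ddm_fit_mle <- function(data, drift_by = "trial_type",
                        min_per_condition = 20) {
  prep <- .ddm_prepare(data, drift_by)
  cnt <- table(prep$cond)
  if (any(cnt < min_per_condition)) {
    stop("fewer than ", min_per_condition, " trials in condition(s): ",
         paste(prep$levels[as.integer(names(cnt))[cnt < min_per_condition]],
               collapse = ", "))
  }
  if (length(unique(prep$upper)) == 1 || sd(prep$rt) < 1e-12) {
    warning("degenerate data (single boundary or constant RTs); ",
            "fit may be unreliable")
  }
  K <- length(prep$levels)
  min_rt <- min(prep$rt)
  start <- c(vapply(seq_len(K), function(k) {
    p <- mean(prep$upper[prep$cond == k])
    2 * (p - 0.5) * 2
  }, numeric(1)), 1.5, 0.7 * min_rt)
  lower <- c(rep(-10, K), 0.2, 0.01)
  upper_b <- c(rep(10, K), 6, max(min_rt - 1e-3, 0.011))
  obj <- function(theta) {
    .ddm_negll(prep$rt, prep$upper, prep$cond,
               theta[seq_len(K)], theta[K + 1], theta[K + 2])
  }
  fit <- optim(start, obj, method = "L-BFGS-B", lower = lower,
               upper = upper_b, control = list(maxit = 500))
  structure(list(
    drift = setNames(fit$par[seq_len(K)], prep$levels),
    a = fit$par[K + 1], t0 = fit$par[K + 2],
    logLik = -fit$value, n = length(prep$rt),
    convergence = fit$convergence
  ), class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("Condition-level diffusion fit (MLE), n = %d, logLik = %.2f\n",
              x$n, x$logLik))
  cat(sprintf("  a = %.3f, t0 = %.3f\n", x$a, x$t0))
  cat("  drift toward goal-consistent response:\n")
  for (nm in names(x$drift)) cat(sprintf("    %s: %.3f\n", nm, x$drift[nm]))
  invisible(x)
}

#' Bayesian condition-level diffusion fit
#'
#' Random-walk Metropolis sampling over the same parameterization as
#' [ddm_fit_mle()], with weakly informative priors: normal on each drift,
#' truncated normal on boundary separation and non-decision time. One
#' chain; convergence assessed by the split-half potential scale reduction
#' statistic (flagged, not silenced, above 1.1).
#'
#' @inheritParams ddm_fit_mle
#' @param n_samples total MCMC draws (default 10000).
#' @param burn_in initial draws discarded (default 5000).
#' @param seed optional integer seed.
#' @param proposal_sd named list overriding proposal standard deviations
#'   (`v`, `a`, `t0`).
#' @return an object of class `ddm_bayes_fit`: `samples` (matrix of kept
#'   draws, one column per parameter), `mean` (posterior means), `rhat`,
#'   `accept_rate`, `converged`.
#' @export
ddm_fit_bayes <- function(data, drift_by = "trial_type",
                          n_samples = 10000, burn_in = 5000, seed = NULL,
                          proposal_sd = list(), min_per_condition = 20) {
  stopifnot(burn_in < n_samples)
  if (!is.null(seed)) set.seed(seed)
  prep <- .ddm_prepare(data, drift_by)
  cnt <- table(prep$cond)
  if (any(cnt < min_per_condition)) {
    stop("fewer than ", min_per_condition, " trials per condition")
  }
  K <- length(prep$levels)
  min_rt <- min(prep$rt)
  sd_v <- if (!is.null(proposal_sd$v)) proposal_sd$v else 0.12
  sd_a <- if (!is.null(proposal_sd$a)) proposal_sd$a else 0.05
  sd_t0 <- if (!is.null(proposal_sd$t0)) proposal_sd$t0 else 0.008
  step <- c(rep(sd_v, K), sd_a, sd_t0)
  log_post <- function(theta) {
    v <- theta[seq_len(K)]
    a <- theta[K + 1]
    t0 <- theta[K + 2]
    if (a <= 0.2 || t0 <= 0.01 || t0 >= min_rt) return(-Inf)
    lp <- sum(dnorm(v, 0, 5, log = TRUE)) +
      dnorm(a, 1.5, 2, log = TRUE) + dnorm(t0, 0.3, 0.5, log = TRUE)
    nll <- .ddm_negll(prep$rt, prep$upper, prep$cond, v, a, t0)
    if (nll >= 1e10) return(-Inf)
    lp - nll
  }
  # start from the MLE for fast burn-in
  mle <- ddm_fit_mle(data, drift_by, min_per_condition)
  theta <- c(mle$drift, mle$a, mle$t0)
  lp <- log_post(theta)
  keep <- matrix(NA_real_, n_samples - burn_in, K + 2)
  colnames(keep) <- c(prep$levels, "a", "t0")
  acc <- 0L
  for (i in seq_len(n_samples)) {
    prop <- theta + rnorm(K + 2, 0, step)
    lp_prop <- log_post(prop)
    if (log(runif(1)) < lp_prop - lp) {
      theta <- prop
      lp <- lp_prop
      acc <- acc + 1L
    }
    if (i > burn_in) keep[i - burn_in, ] <- theta
  }
  rhat <- apply(keep, 2, .split_rhat)
  converged <- all(rhat < 1.1, na.rm = TRUE)
  if (!converged) {
    warning("split-chain diagnostic exceeds 1.1 for: ",
            paste(colnames(keep)[rhat >= 1.1], collapse = ", "))
  }
  structure(list(samples = keep, mean = colMeans(keep), rhat = rhat,
                 accept_rate = acc / n_samples, converged = converged,
                 n = length(prep$rt)),
            class = "ddm_bayes_fit")
}

#' @export
print.ddm_bayes_fit <- function(x, ...) {
  cat(sprintf(
    "Bayesian diffusion fit: %d kept draws, acceptance %.2f, %s\n",
    nrow(x$samples), x$accept_rate,
    if (x$converged) "converged" else "NOT converged"))
  print(round(x$mean, 3))
  invisible(x)
}

# Split-half potential scale reduction on one chain.
.split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  a <- x[seq_len(n)]
  b <- x[seq_len(n) + n]
  W <- (var(a) + var(b)) / 2
  B <- n * var(c(mean(a), mean(b)))
  if (!is.finite(W) || W < 1e-300) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Highest density interval of a sample
#'
#' Narrowest interval containing the stated probability mass.
#'
#' @param x numeric sample.
#' @param mass probability mass (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @export
hdi <- function(x, mass = 0.95) {
  stopifnot(mass > 0, mass <= 1)
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(mass * n)
  if (m >= n) return(c(xs[1], xs[n]))
  starts <- seq_len(n - m + 1)
  widths <- xs[starts + m - 1] - xs[starts]
  i <- which.min(widths)
  c(xs[i], xs[i + m - 1])
}

#' Posterior difference distribution and its highest density interval
#'
#' Pairwise subtraction of two equal-length posterior sample arrays (in
#' their original order), returning the HDI of the difference and its
#' classification: whether the interval contains zero, lies strictly below
#' zero, or strictly above.
#'
#' @param samples_a,samples_b equal-length numeric sample vectors.
#' @param mass HDI probability mass (default 0.95).
#' @return list with `interval` (`c(lower, upper)`), `classification`
#'   (`"contains zero"`, `"strictly negative"`, `"strictly positive"`),
#'   and `mean_difference`.
#' @export
posterior_difference_hdi <- function(samples_a, samples_b, mass = 0.95) {
  if (length(samples_a) != length(samples_b)) {
    stop("sample arrays must have equal length")
  }
  d <- samples_a - samples_b
  iv <- hdi(d, mass)
  cls <- if (iv[1] > 0) {
    "strictly positive"
  } else if (iv[2] < 0) {
    "strictly negative"
  } else {
    "contains zero"
  }
  list(interval = iv, classification = cls, mean_difference = mean(d))
}

#' Parameter-change report across EITHER-frequency groups
#'
#' For each shared parameter and each consecutive pair of group-level
#' Bayesian fits, reports the 95% HDI of the posterior difference
#' (lower-frequency group minus higher) and its classification -- the
#' standard report of whether diffusion parameters change across the
#' between-participants manipulation.
#'
#' @param fits named list of [ddm_fit_bayes()] results, names giving group
#'   labels in increasing EITHER-frequency order.
#' @param mass HDI probability mass.
#' @return data.frame with `parameter`, `pair`, `lower`, `upper`,
#'   `classification`.
#' @export
posterior_difference_table <- function(fits, mass = 0.95) {
  stopifnot(length(fits) >= 2, !is.null(names(fits)))
  out <- list()
  for (i in seq_len(length(fits) - 1)) {
    a <- fits[[i]]
    b <- fits[[i + 1]]
    common <- intersect(colnames(a$samples), colnames(b$samples))
    for (p in common) {
      pd <- posterior_difference_hdi(a$samples[, p], b$samples[, p], mass)
      out[[length(out) + 1L]] <- data.frame(
        parameter = p,
        pair = paste(names(fits)[i], "-", names(fits)[i + 1]),
        lower = pd$interval[1], upper = pd$interval[2],
        classification = pd$classification
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Condition-level diffusion fits per group
#'
#' Convenience wrapper: filters to the Transfer Phase, drops non-task
#' responses, and fits drift per trial type within each EITHER-frequency
#' group (threshold and non-decision time shared within group).
#'
#' @param data behavioral data.frame (any phases; only transfer rows with
#'   CN/WR responses are used).
#' @param method `"mle"` or `"bayes"`.
#' @param ... passed to [ddm_fit_mle()] or [ddm_fit_bayes()].
#' @return list with `fits` (one fit per group) and, for MLE, `drift`
#'   (data.frame of group, trial type, fitted drift toward the
#'   goal-consistent response).
#' @export
ddm_condition_fit <- function(data, method = c("mle", "bayes"), ...) {
  method <- match.arg(method)
  tr <- data[data$phase == "transfer" &
               data$response_task %in% c("CN", "WR"), , drop = FALSE]
  groups <- sort(unique(tr$group))
  fits <- lapply(groups, function(g) {
    sub <- tr[tr$group == g, , drop = FALSE]
    if (method == "mle") ddm_fit_mle(sub, "trial_type", ...)
    else ddm_fit_bayes(sub, "trial_type", ...)
  })
  names(fits) <- as.character(groups)
  drift <- NULL
  if (method == "mle") {
    drift <- do.call(rbind, lapply(names(fits), function(g) {
      data.frame(group = as.integer(g),
                 trial_type = names(fits[[g]]$drift),
                 v = unname(fits[[g]]$drift))
    }))
  }
  structure(list(fits = fits, drift = drift, method = method),
            class = "ddm_condition_fit")
}
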