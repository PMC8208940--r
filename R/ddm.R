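#' Drift rate from a control signal
#'
#' The drift is a control-weighted mixture of the controlled (color naming)
#' and automatic (word reading) pathways:
#' `d = c * y_color * d_controlled + (1 - c) * y_word * d_automatic`,
#' where `y_color`, `y_word` in \{-1, +1\} code the response boundary
#' associated with the stimulus color and word. On incongruent stimuli the
#' two pathways point to opposite boundaries (`y_color = -y_word`). The
#' package's coordinate convention puts the color (CN) response at the upper
#' boundary (`y_color = +1`).
#'
#' @param c control signal intensity in \[0, 1\] (vectorized).
#' @param y_color,y_word boundary codes, each -1 or +1.
#' @param d_controlled,d_automatic pathway drift magnitudes (1/s).
#' @return drift rate(s).
#' @examples
#' drift_from_control(0.5, +1, -1, 1.32, 3.22)  # -0.95
#' @export
drift_from_control <- function(c, y_color = +1, y_word = -1,
                               d_controlled = 1.32, d_automatic = 3.22) {
  stopifnot(all(c >= 0 & c <= 1),
            all(y_color %in% c(-1, 1)), all(y_word %in% c(-1, 1)))
  c * y_color * d_controlled + (1 - c) * y_word * d_automatic
}

#' Diffusion process parameters
#'
#' Two-boundary diffusion between 0 and `a`, starting at `z`, with drift `v`,
#' within-trial noise `s`, non-decision time `t0`, Euler step `dt`, and a
#' response deadline.
#'
#' @param v drift rate (evidence/s).
#' @param a boundary separation (> 0).
#' @param z starting point, strictly between 0 and `a` (default `a/2`).
#' @param s within-trial noise (diffusion coefficient); fixed at 1 by the
#'   usual scaling convention unless fitted.
#' @param t0 non-decision time (s).
#' @param dt Euler-Maruyama step (s).
#' @param deadline response deadline (s); walks that do not absorb by
#'   `deadline - t0` time out.
#' @return an object of class `ddm_params`.
#' @export
ddm_params <- function(v, a, z = a / 2, s = 1, t0 = 0.3, dt = 0.001,
                       deadline = 3) {
  stopifnot(a > 0, z > 0, z < a, s > 0, dt > 0, t0 >= 0, deadline > t0)
  structure(list(v = v, a = a, z = z, s = s, t0 = t0, dt = dt,
                 deadline = deadline),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "Diffusion parameters: v = %.3f, a = %.3f, z = %.3f, s = %.3f, t0 = %.3f\n",
    x$v, x$a, x$z, x$s, x$t0))
  invisible(x)
}

#' Simulate diffusion trials
#'
#' Euler-Maruyama walk from `z` with increments `v*dt + s*sqrt(dt)*xi` until
#' a boundary is crossed or the deadline is reached.
#'
#' @param params a [ddm_params()] object.
#' @param n number of trials.
#' @param seed optional integer seed.
#' @return data.frame with columns `boundary` (`"upper"`, `"lower"`, or `NA`
#'   on timeout), `rt` (seconds, including `t0`), `timed_out`.
#' @export
ddm_simulate <- function(params, n = 1, seed = NULL) {
  stopifnot(inherits(params, "ddm_params"))
  if (!is.null(seed)) set.seed(seed)
  out <- cpp_ddm_simulate(as.integer(n), params$v, params$a, params$z,
                          params$s, params$t0, params$dt, params$deadline)
  data.frame(
    boundary = c("lower", "upper")[match(out$boundary, c(0L, 1L))],
    rt = out$rt, timed_out = out$timed_out,
    stringsAsFactors = FALSE
  )
}

#' Analytic probability of absorbing at the upper boundary
#'
#' `(1 - exp(-2 v z / s^2)) / (1 - exp(-2 v a / s^2))` for nonzero drift;
#' `z / a` for zero drift.
#'
#' @param params a [ddm_params()] object.
#' @return probability of an upper-boundary response (ignoring the deadline).
#' @export
ddm_choice_probability <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  q <- 2 * params$v / params$s^2
  if (abs(q) < 1e-12) return(params$z / params$a)
  qa <- q * params$a
  if (qa < -500) return(exp(q * (params$a - params$z)))
  if (qa > 500) return(1 - exp(-q * params$z))
  expm1(-q * params$z) / expm1(-q * params$a)
}

#' Mean decision time (exclusive of non-decision time)
#'
#' Closed-form expected first-passage time of the two-boundary diffusion,
#' `E[T] = (a/v) * P(upper) - z/v` for nonzero drift and `z (a - z) / s^2`
#' for zero drift. For `z = a/2` this reduces to
#' `(a / 2v) * tanh(v a / 2 s^2)`.
#'
#' @param params a [ddm_params()] object.
#' @return expected decision time in seconds.
#' @export
ddm_mean_decision_time <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  if (abs(params$v) < 1e-12) {
    return(params$z * (params$a - params$z) / params$s^2)
  }
  (params$a / params$v) * ddm_choice_probability(params) - params$z / params$v
}

# First-passage density at the *lower* boundary of a unit diffusion on
# [0, 1] started at relative position w, evaluated at normalized time u.
# Small-time and large-time series with Navarro-Fuss style truncation.
.wfpt_f0 <- function(u, w, err = 1e-10) {
  if (u <= 0) return(0)
  # required terms for each expansion
  if (2 * pi * u * err < 1) {
    kl <- max(sqrt(-2 * log(pi * u * err) / (pi^2 * u)), 1 / (pi * sqrt(u)))
  } else {
    kl <- 1 / (pi * sqrt(u))
  }
  if (2 * sqrt(2 * pi * u) * err < 1) {
    ks <- max(2 + sqrt(-2 * u * log(2 * sqrt(2 * pi * u) * err)), sqrt(u) + 1)
  } else {
    ks <- 2
  }
  if (ks < kl) {
    K <- ceiling(ks)
    k <- seq(-floor((K - 1) / 2), ceiling((K - 1) / 2))
    sum((w + 2 * k) * exp(-(w + 2 * k)^2 / (2 * u))) / sqrt(2 * pi * u^3)
  } else {
    K <- ceiling(kl)
    k <- seq_len(K)
    pi * sum(k * exp(-k^2 * pi^2 * u / 2) * sin(k * pi * w))
  }
}

#' Wiener first-passage time density
#'
#' Defective density of hitting the given boundary at time `t`, for the
#' two-boundary diffusion; integrates over `t` to the corresponding
#' [ddm_choice_probability()]. Evaluated by the standard small-time /
#' large-time series pair with automatic truncation.
#'
#' @param t time(s) at which to evaluate (seconds, including `t0`); density
#'   is 0 for `t <= t0`.
#' @param params a [ddm_params()] object.
#' @param boundary `"upper"` or `"lower"`.
#' @return density values, same length as `t`.
#' @export
ddm_fpt_density <- function(t, params, boundary = c("upper", "lower")) {
  stopifnot(inherits(params, "ddm_params"))
  boundary <- match.arg(boundary)
  # scale noise to 1
  v <- params$v / params$s
  a <- params$a / params$s
  w <- params$z / params$a
  if (boundary == "upper") {
    v <- -v
    w <- 1 - w
  }
  tau <- t - params$t0
  out <- numeric(length(t))
  pos <- which(tau > 0)
  for (i in pos) {
    u <- tau[i] / a^2
    out[i] <- exp(-v * a * w - v^2 * tau[i] / 2) / a^2 * .wfpt_f0(u, w)
  }
  out
}
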