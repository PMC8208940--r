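#' Stimulus-response associator state
#'
#' Rescorla-Wagner learner over 16 indicator features (8 colors, 8 words)
#' and the two task responses. Associations start at zero.
#'
#' @param alpha learning rate in \[0, 1\].
#' @param responses response labels (default the two tasks, matching how
#'   choices are scored in the analyses; an 8-key response space can be
#'   passed instead).
#' @return an object of class `sr_state`.
#' @export
sr_state <- function(alpha = 0.1, responses = c("CN", "WR")) {
  stopifnot(alpha >= 0, alpha <= 1, length(responses) >= 2)
  A <- matrix(0, nrow = 16, ncol = length(responses),
              dimnames = list(c(paste0("color_", .lvoc_labels),
                                paste0("word_", .lvoc_labels)),
                              responses))
  structure(list(A = A, alpha = alpha), class = "sr_state")
}

.sr_active <- function(stimulus) {
  c(.label_index(stimulus$color), 8L + .label_index(stimulus$word))
}

#' Prediction-error update of stimulus-response associations
#'
#' For the chosen response `a`, each active feature's association moves
#' toward the reward by the prediction error:
#' `A[f, a] <- A[f, a] + alpha * (R - sum_f' f'(s) A[f', a])`.
#' Associations of inactive features and other responses are unchanged.
#'
#' @param state an [sr_state()].
#' @param stimulus list with `color` and `word`.
#' @param response the chosen response label.
#' @param reward points received.
#' @return the updated `sr_state`.
#' @export
sr_update <- function(state, stimulus, response, reward) {
  stopifnot(inherits(state, "sr_state"),
            response %in% colnames(state$A))
  act <- .sr_active(stimulus)
  pred <- sum(state$A[act, response])
  state$A[act, response] <- state$A[act, response] +
    state$alpha * (reward - pred)
  state
}

#' Choice probabilities under the exponentiated Luce rule
#'
#' `P(a) = exp(sum_f A[f,a] f(s)) / sum_a' exp(sum_f A[f,a'] f(s))`,
#' computed with max-subtraction for overflow safety (value-preserving).
#'
#' @inheritParams sr_update
#' @return named probability vector over responses.
#' @export
sr_choice_prob <- function(state, stimulus) {
  stopifnot(inherits(state, "sr_state"))
  act <- .sr_active(stimulus)
  score <- colSums(state$A[act, , drop = FALSE])
  e <- exp(score - max(score))
  e / sum(e)
}

#' Simulate the stimulus-response model over a schedule
#'
#' @param schedule an experiment schedule (one or more participants).
#' @param alpha learning rate.
#' @param seed optional integer seed.
#' @return the schedule with `response_task`, `points_earned`, `rewarded`
#'   columns appended (state resets per participant).
#' @export
sr_simulate <- function(schedule, alpha = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pieces <- lapply(split(schedule, schedule$participant), function(sub) {
    sub <- sub[order(sub$trial_index), , drop = FALSE]
    st <- sr_state(alpha)
    resp <- character(nrow(sub))
    pts <- numeric(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      stim <- list(color = sub$color[i], word = sub$word[i])
      p <- sr_choice_prob(st, stim)
      resp[i] <- sample(names(p), 1, prob = p)
      pts[i] <- if (resp[i] == sub$rewarded_task[i]) sub$points[i] else 0
      st <- sr_update(st, stim, resp[i], pts[i])
    }
    sub$response_task <- resp
    sub$points_earned <- pts
    sub$rewarded <- pts > 0
    sub
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# Log-likelihood of observed responses under the S-R model, replaying the
# observed choices and rewards through the learner.
.sr_loglik <- function(data, alpha) {
  ll <- 0
  for (sub in split(data, data$participant)) {
    sub <- sub[order(sub$trial_index), , drop = FALSE]
    st <- sr_state(alpha)
    for (i in seq_len(nrow(sub))) {
      if (!sub$response_task[i] %in% colnames(st$A)) next
      stim <- list(color = sub$color[i], word = sub$word[i])
      p <- sr_choice_prob(st, stim)
      ll <- ll + log(max(p[[sub$response_task[i]]], 1e-300))
      st <- sr_update(st, stim, sub$response_task[i],
                      if (sub$response_task[i] == sub$rewarded_task[i])
                        sub$points[i] else 0)
    }
  }
  ll
}

#' Fit the stimulus-response model by maximum likelihood
#'
#' Optimizes the single learning-rate parameter over \[0, 1\].
#'
#' @param data behavioral data.frame (`participant`, `trial_index`,
#'   `color`, `word`, `response_task`, `rewarded_task`, `points`).
#' @return list of class `model_fit`: `model`, `estimates`, `logLik`, `k`,
#'   `n`, `bic`.
#' @export
sr_fit <- function(data) {
  n <- sum(data$response_task %in% c("CN", "WR"))
  opt <- optimize(function(a) -.sr_loglik(data, a), c(1e-4, 1))
  structure(list(model = "sr",
                 estimates = c(alpha = opt$minimum),
                 logLik = -opt$objective, k = 1L, n = n,
                 bic = bic(-opt$objective, 1L, n)),
            class = "model_fit")
}

#' Win-stay-lose-shift choice
#'
#' Repeats the previous task after a rewarded trial, switches after an
#' unrewarded one; the first trial is a uniform random choice.
#'
#' @param state list with `last_task` (`"CN"`, `"WR"`, or `"none"`) and
#'   `last_rewarded` (logical).
#' @return `"CN"` or `"WR"`.
#' @export
wsls_choose <- function(state) {
  if (identical(state$last_task, "none")) {
    return(sample(c("CN", "WR"), 1))
  }
  if (isTRUE(state$last_rewarded)) {
    state$last_task
  } else {
    setdiff(c("CN", "WR"), state$last_task)
  }
}

#' Simulate the win-stay-lose-shift model over a schedule
#'
#' @inheritParams sr_simulate
#' @param epsilon lapse probability of deviating from the WSLS rule.
#' @return the schedule with behavioral columns appended.
#' @export
wsls_simulate <- function(schedule, epsilon = 0, seed = NULL) {
  stopifnot(epsilon >= 0, epsilon < 1)
  if (!is.null(seed)) set.seed(seed)
  pieces <- lapply(split(schedule, schedule$participant), function(sub) {
    sub <- sub[order(sub$trial_index), , drop = FALSE]
    st <- list(last_task = "none", last_rewarded = NA)
    resp <- character(nrow(sub))
    pts <- numeric(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      r <- wsls_choose(st)
      if (runif(1) < epsilon) r <- setdiff(c("CN", "WR"), r)
      resp[i] <- r
      pts[i] <- if (r == sub$rewarded_task[i]) sub$points[i] else 0
      st <- list(last_task = r, last_rewarded = pts[i] > 0)
    }
    sub$response_task <- resp
    sub$points_earned <- pts
    sub$rewarded <- pts > 0
    sub
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Fit the win-stay-lose-shift model
#'
#' The likelihood assigns probability `1 - epsilon` to the response the
#' WSLS rule predicts and `epsilon` to the other task (first trials are
#' 50/50); a strictly deterministic rule would have zero likelihood on any
#' violation, so the single lapse parameter is fitted, and its maximum
#' likelihood estimate is the observed violation rate.
#'
#' @inheritParams sr_fit
#' @return a `model_fit` list (see [sr_fit()]).
#' @export
wsls_fit <- function(data) {
  n_first <- 0L
  n_pred <- 0L
  n_viol <- 0L
  for (sub in split(data, data$participant)) {
    sub <- sub[order(sub$trial_index), , drop = FALSE]
    st <- list(last_task = "none", last_rewarded = NA)
    for (i in seq_len(nrow(sub))) {
      obs <- sub$response_task[i]
      if (!obs %in% c("CN", "WR")) next
      if (identical(st$last_task, "none")) {
        n_first <- n_first + 1L
      } else {
        pred <- if (isTRUE(st$last_rewarded)) st$last_task else
          setdiff(c("CN", "WR"), st$last_task)
        n_pred <- n_pred + 1L
        if (obs != pred) n_viol <- n_viol + 1L
      }
      st <- list(last_task = obs,
                 last_rewarded = obs == sub$rewarded_task[i])
    }
  }
  eps <- if (n_pred > 0) n_viol / n_pred else 0.5
  eps_c <- min(max(eps, 1e-6), 1 - 1e-6)
  ll <- n_first * log(0.5) + n_viol * log(eps_c) +
    (n_pred - n_viol) * log(1 - eps_c)
  n <- n_first + n_pred
  structure(list(model = "wsls", estimates = c(epsilon = eps),
                 logLik = ll, k = 1L, n = n, bic = bic(ll, 1L, n)),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s model fit: logLik = %.2f, k = %d, n = %d, BIC = %.2f\n",
              toupper(x$model), x$logLik, x$k, x$n, x$bic))
  print(round(x$estimates, 4))
  invisible(x)
}

#' Bayesian Information Criterion
#'
#' `k * log(n) - 2 * logLik`.
#'
#' @param log_likelihood maximized log-likelihood.
#' @param k_params number of free parameters.
#' @param n_obs number of observations (>= 1).
#' @return BIC value.
#' @export
bic <- function(log_likelihood, k_params, n_obs) {
  stopifnot(n_obs >= 1)
  k_params * log(n_obs) - 2 * log_likelihood
}

#' Compare comparator models on response data
#'
#' Fits the stimulus-response and win-stay-lose-shift models to the same
#' trial-level choices and reports their goodness of fit.
#'
#' @param data behavioral data.frame of observed choices.
#' @param models subset of `c("sr", "wsls")`.
#' @return data.frame with `model`, `logLik`, `k`, `n`, `bic`, sorted by
#'   BIC (best first).
#' @export
compare_models <- function(data, models = c("sr", "wsls")) {
  fits <- lapply(models, function(m) {
    switch(m, sr = sr_fit(data), wsls = wsls_fit(data),
           stop("unknown model: ", m))
  })
  out <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f$model, logLik = f$logLik, k = f$k, n = f$n,
               bic = f$bic)
  }))
  out[order(out$bic), , drop = FALSE]
}
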