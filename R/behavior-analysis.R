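#' Timing constants of the task
#'
#' Used by the reward-rate computation: each trial occupies the response
#' time plus the feedback display and the intertrial interval.
#'
#' @param deadline response deadline (s).
#' @param feedback feedback display duration (s).
#' @param iti intertrial interval (s).
#' @return a list of timing constants.
#' @export
timing_config <- function(deadline = 3, feedback = 1, iti = 0.1) {
  stopifnot(deadline > 0, feedback >= 0, iti >= 0)
  list(deadline = deadline, feedback = feedback, iti = iti)
}

#' Apply the standard trial filters
#'
#' Removes trials without a response by the deadline (timeouts) and trials
#' answered with a key matching neither displayed feature (`other_key`).
#' Reward-rate computations deliberately bypass this filter and keep all
#' trials.
#'
#' @param data behavioral data.frame with a `response_task` column
#'   (values among `"CN"`, `"WR"`, `"other_key"`, `"timeout"`) and/or a
#'   `timed_out` column.
#' @return a list with elements `data` (retained rows) and `exclusions`
#'   (data.frame of counts per reason).
#' @export
apply_filters <- function(data) {
  if (!"response_task" %in% names(data)) {
    stop("data must contain a 'response_task' column")
  }
  timeout <- data$response_task == "timeout" |
    (if ("timed_out" %in% names(data)) data$timed_out else FALSE)
  other <- !timeout & data$response_task == "other_key"
  keep <- !timeout & !other
  if (!any(keep)) warning("all trials excluded by the filters")
  list(
    data = data[keep, , drop = FALSE],
    exclusions = data.frame(
      reason = c("timeout", "other_key"),
      n = c(sum(timeout), sum(other))
    )
  )
}

#' Goal-inconsistent response rate by condition
#'
#' Fraction of responses to the feature of the unrewarded task
#' (`response_task != rewarded_task`), per grouping cell. Expects filtered
#' data (responses only `"CN"`/`"WR"`).
#'
#' @param data filtered behavioral data.frame.
#' @param by character vector of grouping columns (default trial type by
#'   group).
#' @return data.frame with the grouping columns, `n` (trials), and
#'   `goal_inconsistent_rate`; cells absent from the data are simply not
#'   listed.
#' @export
goal_inconsistent_rate <- function(data, by = c("trial_type", "group")) {
  stopifnot(all(c(by, "response_task", "rewarded_task") %in% names(data)))
  inconsistent <- as.numeric(data$response_task != data$rewarded_task)
  agg <- aggregate(inconsistent, data[, by, drop = FALSE],
                   function(x) c(n = length(x), rate = mean(x)))
  out <- cbind(agg[, by, drop = FALSE],
               n = agg$x[, "n"],
               goal_inconsistent_rate = agg$x[, "rate"])
  rownames(out) <- NULL
  out
}

#' Transfer-phase reward rate per participant
#'
#' Sum of rewards divided by total time on task in the Transfer Phase
#' (excluding breaks): each trial contributes its response time plus the
#' feedback duration and intertrial interval. All trials are kept,
#' including timeouts (which contribute the full deadline and zero points).
#'
#' @param data behavioral data.frame with `phase`, `participant`,
#'   `points_earned`, `rt` columns (and optionally `group`).
#' @param timing a [timing_config()] object.
#' @return data.frame with `participant` (and `group` if present) and
#'   `reward_rate` in points per second.
#' @export
reward_rate <- function(data, timing = timing_config()) {
  tr <- data[data$phase == "transfer", , drop = FALSE]
  if (nrow(tr) == 0) stop("no transfer-phase rows in data")
  tr$time <- tr$rt + timing$feedback + timing$iti
  by <- intersect(c("participant", "group"), names(tr))
  pts <- aggregate(tr[, c("points_earned", "time")],
                   tr[, by, drop = FALSE], sum)
  if (any(pts$time <= 0)) stop("zero total time on task")
  pts$reward_rate <- pts$points_earned / pts$time
  pts[, c(by, "reward_rate")]
}

#' Moving average of a series
#'
#' Trailing (default) or centered mean over a fixed window; entries without
#' a full window are `NA`, so a trailing window of width `w` leaves the
#' first `w - 1` entries undefined.
#'
#' @param x numeric series.
#' @param window window width (>= 1, <= length of series).
#' @param align `"trailing"` or `"centered"`.
#' @return numeric vector of the same length as `x`.
#' @examples
#' moving_average(c(0, 1, 0, 1, 0, 1), 3)
#' @export
moving_average <- function(x, window = 3, align = c("trailing", "centered")) {
  align <- match.arg(align)
  stopifnot(window >= 1, window <= length(x))
  sides <- if (align == "trailing") 1 else 2
  as.numeric(stats::filter(x, rep(1 / window, window), sides = sides))
}
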