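#' Build the feature-task mapping for the rewarded Stroop experiment
#'
#' Assigns each of the four colors and four words of experimental interest
#' (yellow, green, red, blue) to be CN-mapped (color naming rewarded) or
#' WR-mapped (word reading rewarded), two of each. The four control features
#' (white, orange, brown, pink) are never task-mapped during training; they
#' are instead split between the two transfer-phase control trial types so
#' that WR CONTROL and CN CONTROL stimuli share no features.
#'
#' The default (no seed) is the canonical assignment: colors red and blue
#' CN-mapped, yellow and green WR-mapped, with the word assignment matching
#' the color assignment label-for-label. Matching labels guarantees that
#' every transfer trial type has a unique-stimulus count that divides its
#' trial count exactly (BOTH and NEITHER then have 2 unique stimuli each,
#' EITHER-COLOR and EITHER-WORD 4 each).
#'
#' @param assignment_seed optional integer seed; when given, the CN/WR split
#'   of colors (and, if `word_split = "random"`, of words) is drawn at random.
#' @param word_split `"match_colors"` (default) assigns each word the same
#'   mapping as the like-named color; `"random"` draws an independent 2/2
#'   split of the words of interest.
#' @return an object of class `feature_mapping`: a list with character
#'   vectors `cn_colors`, `wr_colors`, `cn_words`, `wr_words`,
#'   `wr_control_colors`, `cn_control_colors`, `wr_control_words`,
#'   `cn_control_words`.
#' @examples
#' build_feature_mapping()
#' build_feature_mapping(assignment_seed = 7, word_split = "random")
#' @export
build_feature_mapping <- function(assignment_seed = NULL,
                                  word_split = c("match_colors", "random")) {
  word_split <- match.arg(word_split)
  interest <- .interest_features
  ctrl <- .control_features
  if (is.null(assignment_seed)) {
    cn_colors <- c("red", "blue")
    wr_ctrl_colors <- c("white", "orange")
  } else {
    set.seed(assignment_seed)
    cn_colors <- sort(sample(interest, 2L))
    wr_ctrl_colors <- sort(sample(ctrl, 2L))
  }
  wr_colors <- setdiff(interest, cn_colors)
  cn_ctrl_colors <- setdiff(ctrl, wr_ctrl_colors)
  if (word_split == "match_colors") {
    cn_words <- cn_colors
  } else {
    cn_words <- sort(sample(interest, 2L))
  }
  wr_words <- setdiff(interest, cn_words)
  out <- list(
    cn_colors = cn_colors, wr_colors = wr_colors,
    cn_words = cn_words, wr_words = wr_words,
    wr_control_colors = wr_ctrl_colors,
    cn_control_colors = cn_ctrl_colors,
    wr_control_words = wr_ctrl_colors,
    cn_control_words = cn_ctrl_colors
  )
  class(out) <- "feature_mapping"
  out
}

#' @export
print.feature_mapping <- function(x, ...) {
  cat("Feature-task mapping (rewarded Stroop)\n")
  cat("  CN-mapped colors:", paste(x$cn_colors, collapse = ", "), "\n")
  cat("  WR-mapped colors:", paste(x$wr_colors, collapse = ", "), "\n")
  cat("  CN-mapped words: ", paste(x$cn_words, collapse = ", "), "\n")
  cat("  WR-mapped words: ", paste(x$wr_words, collapse = ", "), "\n")
  cat("  WR CONTROL features:",
      paste(unique(c(x$wr_control_colors, x$wr_control_words)),
            collapse = ", "), "\n")
  cat("  CN CONTROL features:",
      paste(unique(c(x$cn_control_colors, x$cn_control_words)),
            collapse = ", "), "\n")
  invisible(x)
}

# All incongruent (color, word) combinations of two label sets.
.cross_stimuli <- function(colors, words) {
  g <- expand.grid(color = colors, word = words,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[g$color != g$word, , drop = FALSE]
}

# Round-robin repetition of unique stimuli to n trials, then shuffled by the
# caller. Counts differ by at most one when n is not divisible.
.balanced_rows <- function(stimuli, n) {
  k <- nrow(stimuli)
  stimuli[rep_len(seq_len(k), n), , drop = FALSE]
}

#' Generate one part of the Mapping Phase
#'
#' Part 1 pairs the four colors of interest with the four control words and
#' rewards the task mapped to the stimulus color; part 2 pairs the four words
#' of interest with the four control colors and rewards the task mapped to
#' the word. Every unique stimulus appears equally often; rewarded responses
#' earn 5 points.
#'
#' @param mapping a [build_feature_mapping()] object.
#' @param part 1 or 2.
#' @param n_trials number of trials; must be divisible by the number of
#'   unique stimuli (16).
#' @param seed optional integer seed for the trial-order shuffle.
#' @return a data.frame of trial specifications with columns `phase`,
#'   `trial_type`, `color`, `word`, `rewarded_task`, `points`.
#' @export
generate_mapping_phase <- function(mapping, part, n_trials = 160, seed = NULL) {
  stopifnot(inherits(mapping, "feature_mapping"), part %in% c(1L, 2L))
  if (part == 1) {
    stim <- .cross_stimuli(.interest_features, .control_features)
    rewarded <- ifelse(stim$color %in% mapping$cn_colors, "CN", "WR")
  } else {
    stim <- .cross_stimuli(.control_features, .interest_features)
    rewarded <- ifelse(stim$word %in% mapping$cn_words, "CN", "WR")
  }
  k <- nrow(stim)
  if (n_trials %% k != 0) {
    stop("n_trials (", n_trials, ") must be divisible by the number of ",
         "unique stimuli (", k, ") for a balanced design")
  }
  stim$rewarded_task <- rewarded
  rows <- .balanced_rows(stim, n_trials)
  if (!is.null(seed)) set.seed(seed)
  rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
  data.frame(
    phase = paste0("mapping", part),
    trial_type = ifelse(rows$rewarded_task == "CN", "MAPPING_CN", "MAPPING_WR"),
    color = rows$color, word = rows$word,
    rewarded_task = rows$rewarded_task,
    points = 5L,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Transfer-phase trial-type percentages by EITHER-frequency group.
.transfer_pct <- function(group) {
  group <- as.integer(group)
  if (!group %in% c(0L, 20L, 50L)) {
    stop("group must be one of 0, 20, 50 (percent EITHER trials)")
  }
  c(EITHER = group,
    CN_CONTROL = c(`0` = 50L, `20` = 30L, `50` = 0L)[[as.character(group)]],
    BOTH = 20L, WR_CONTROL = 20L, NEITHER = 10L)
}

#' Transfer-phase trial-type composition for an EITHER-frequency group
#'
#' @param group EITHER-trial percentage: 0, 20, or 50.
#' @param n_trials number of transfer trials (default 200).
#' @return named integer vector of trial counts per trial type, with EITHER
#'   split equally into `EITHER_COLOR` and `EITHER_WORD`.
#' @export
transfer_composition <- function(group, n_trials = 200) {
  pct <- .transfer_pct(group)
  cnt <- pct * n_trials / 100
  if (any(cnt != round(cnt)) || (cnt[["EITHER"]] %% 2 != 0)) {
    stop("trial-type percentages do not yield integer counts for n_trials = ",
         n_trials)
  }
  c(EITHER_COLOR = unname(cnt[["EITHER"]]) %/% 2L,
    EITHER_WORD = unname(cnt[["EITHER"]]) %/% 2L,
    BOTH = unname(cnt[["BOTH"]]),
    NEITHER = unname(cnt[["NEITHER"]]),
    WR_CONTROL = unname(cnt[["WR_CONTROL"]]),
    CN_CONTROL = unname(cnt[["CN_CONTROL"]]))
}

# Unique stimuli and rewarded task for each transfer trial type.
.transfer_stimuli <- function(mapping, type) {
  switch(type,
    BOTH = list(stim = .cross_stimuli(mapping$cn_colors, mapping$cn_words),
                rewarded = "WR"),
    NEITHER = list(stim = .cross_stimuli(mapping$wr_colors, mapping$wr_words),
                   rewarded = "WR"),
    EITHER_COLOR = list(stim = .cross_stimuli(mapping$cn_colors,
                                              mapping$wr_words),
                        rewarded = "CN"),
    EITHER_WORD = list(stim = .cross_stimuli(mapping$wr_colors,
                                             mapping$cn_words),
                       rewarded = "CN"),
    WR_CONTROL = list(stim = .cross_stimuli(mapping$wr_control_colors,
                                            mapping$wr_control_words),
                      rewarded = "WR"),
    CN_CONTROL = list(stim = .cross_stimuli(mapping$cn_control_colors,
                                            mapping$cn_control_words),
                      rewarded = "CN"),
    stop("unknown transfer trial type: ", type)
  )
}

#' Generate the Transfer Phase for one EITHER-frequency group
#'
#' Trial-type counts follow the between-participants frequency manipulation
#' exactly: EITHER trials are 0%, 20%, or 50% of transfer trials by group,
#' BOTH and WR CONTROL are always 20%, NEITHER 10%, and CN CONTROL absorbs
#' the remainder so that color naming is rewarded on exactly half of all
#' transfer trials in every group. All stimuli are novel combinations never
#' shown in the Mapping Phase; rewarded responses earn 10 points.
#'
#' @inheritParams generate_mapping_phase
#' @param group EITHER-trial percentage: 0, 20, or 50.
#' @return a data.frame of trial specifications (columns as in
#'   [generate_mapping_phase()]), `phase = "transfer"`.
#' @export
generate_transfer_phase <- function(mapping, group, n_trials = 200,
                                    seed = NULL) {
  stopifnot(inherits(mapping, "feature_mapping"))
  counts <- transfer_composition(group, n_trials)
  if (!is.null(seed)) set.seed(seed)
  parts <- lapply(names(counts)[counts > 0], function(type) {
    ts <- .transfer_stimuli(mapping, type)
    rows <- .balanced_rows(ts$stim, counts[[type]])
    data.frame(phase = "transfer", trial_type = type,
               color = rows$color, word = rows$word,
               rewarded_task = ts$rewarded, points = 10L,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out[sample.int(nrow(out)), , drop = FALSE]
}

#' Generate full per-participant experiment schedules
#'
#' Each participant completes 520 trials: two 160-trial Mapping Phase parts
#' (colors of interest trained first, then words of interest) followed by a
#' 200-trial Transfer Phase whose composition depends on the participant's
#' EITHER-frequency group. Trial order is randomized within each phase; the
#' phase order is fixed.
#'
#' @param n_participants number of participants to generate.
#' @param group a single EITHER percentage (0, 20, or 50) applied to all
#'   participants, or a vector of length `n_participants`, or `"balanced"`
#'   to cycle participants through 0/20/50.
#' @param seed master integer seed; per-participant seeds are derived from it.
#' @param mapping optional [build_feature_mapping()]; defaults to the
#'   canonical assignment shared by all participants.
#' @param n_mapping,n_transfer trials per mapping part and in transfer.
#' @return a data.frame (the experiment schedule) with columns `participant`,
#'   `group`, `phase`, `trial_index`, `trial_type`, `color`, `word`,
#'   `rewarded_task`, `points`.
#' @examples
#' sched <- generate_experiment(2, group = 50, seed = 1)
#' table(sched$phase) / 2
#' @export
generate_experiment <- function(n_participants, group = "balanced", seed = 1,
                                mapping = NULL,
                                n_mapping = 160, n_transfer = 200) {
  if (is.null(mapping)) mapping <- build_feature_mapping()
  if (identical(group, "balanced")) {
    groups <- rep_len(c(0L, 20L, 50L), n_participants)
  } else {
    groups <- rep_len(as.integer(group), n_participants)
  }
  set.seed(seed)
  pseeds <- sample.int(.Machine$integer.max, n_participants)
  out <- lapply(seq_len(n_participants), function(p) {
    set.seed(pseeds[p])
    m1 <- generate_mapping_phase(mapping, 1, n_mapping)
    m2 <- generate_mapping_phase(mapping, 2, n_mapping)
    tr <- generate_transfer_phase(mapping, groups[p], n_transfer)
    sched <- rbind(m1, m2, tr)
    cbind(participant = p, group = groups[p],
          trial_index = seq_len(nrow(sched)), sched)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("participant", "group", "phase", "trial_index", "trial_type",
          "color", "word", "rewarded_task", "points")]
}

#' Points earned for a response on given trials
#'
#' A response earns the trial's points if and only if it matches the
#' rewarded task; any other response (including the unrewarded task) earns 0.
#'
#' @param trials a schedule data.frame with columns `rewarded_task` and
#'   `points` (one or more rows).
#' @param response_task `"CN"` or `"WR"`, recycled along rows.
#' @return integer vector of points earned.
#' @export
reward_for_response <- function(trials, response_task) {
  stopifnot(all(c("rewarded_task", "points") %in% names(trials)))
  ifelse(rep_len(response_task, nrow(trials)) == trials$rewarded_task,
         trials$points, 0L)
}

#' Write / read an experiment schedule or behavioral table as delimited text
#'
#' Plain tab-separated text with a header row; the canonical interchange
#' format for schedules and trial-level behavioral records.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_schedule` returns the data.frame.
#' @export
write_schedule <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
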