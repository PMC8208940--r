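# Shared fixtures for the test suite. All data are generated in code.

# A balanced XOR reward schedule over the transfer trial types: the four
# XOR cells (EITHER-COLOR, EITHER-WORD, BOTH, NEITHER) equally often,
# 10-point rewards, shuffled order.
xor_schedule <- function(n_trials, mapping = build_feature_mapping(),
                         seed = 1) {
  stopifnot(n_trials %% 4 == 0)
  set.seed(seed)
  types <- c("EITHER_COLOR", "EITHER_WORD", "BOTH", "NEITHER")
  rows <- do.call(rbind, lapply(types, function(ty) {
    ts <- lvoc:::.transfer_stimuli(mapping, ty)
    st <- ts$stim[rep_len(seq_len(nrow(ts$stim)), n_trials / 4), ]
    data.frame(phase = "transfer", trial_type = ty,
               color = st$color, word = st$word,
               rewarded_task = ts$rewarded, points = 10L)
  }))
  rows <- rows[sample.int(nrow(rows)), ]
  cbind(participant = 1L, group = NA_integer_,
        trial_index = seq_len(nrow(rows)), rows)
}

# Single-condition diffusion data in the canonical behavioral format
# (upper boundary coded as the goal-consistent CN response).
ddm_fixture <- function(params, n, seed) {
  sim <- ddm_simulate(params, n, seed = seed)
  sim <- sim[!sim$timed_out, ]
  data.frame(rt = sim$rt,
             response_task = ifelse(sim$boundary == "upper", "CN", "WR"),
             rewarded_task = "CN", trial_type = "X",
             stringsAsFactors = FALSE)
}

# Goal-inconsistent (CN) response rates per trial type x group for one
# simulated cohort's transfer phase.
cohort_cn_rates <- function(beh, pool_either = TRUE) {
  tr <- beh[beh$phase == "transfer" &
              beh$response_task %in% c("CN", "WR"), , drop = FALSE]
  if (pool_either) {
    tr$trial_type[tr$trial_type %in% c("EITHER_COLOR", "EITHER_WORD")] <-
      "EITHER"
  }
  tr$cn <- tr$response_task == "CN"
  aggregate(cn ~ trial_type + group, tr, mean)
}
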