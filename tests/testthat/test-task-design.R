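test_that("feature mapping is a valid 2/2 split and deterministic per seed", {
  interest <- c("yellow", "green", "red", "blue")
  ctrl <- c("white", "orange", "brown", "pink")
  for (s in c(NULL, 1, 7, 123)) {
    m <- build_feature_mapping(assignment_seed = s, word_split = "random")
    expect_length(m$cn_colors, 2)
    expect_length(m$cn_words, 2)
    expect_setequal(c(m$cn_colors, m$wr_colors), interest)
    expect_setequal(c(m$cn_words, m$wr_words), interest)
    # control features are never task-mapped
    expect_false(any(ctrl %in% c(m$cn_colors, m$wr_colors,
                                 m$cn_words, m$wr_words)))
    expect_setequal(c(m$wr_control_colors, m$cn_control_colors), ctrl)
  }
  expect_identical(build_feature_mapping(11), build_feature_mapping(11))
  # canonical default
  m0 <- build_feature_mapping()
  expect_setequal(m0$cn_colors, c("red", "blue"))
  expect_setequal(m0$wr_colors, c("yellow", "green"))
  expect_identical(m0$cn_words, m0$cn_colors)
})

test_that("mapping phase pairs features of interest with control features", {
  m <- build_feature_mapping()
  p1 <- generate_mapping_phase(m, 1, 160, seed = 3)
  p2 <- generate_mapping_phase(m, 2, 160, seed = 4)
  expect_equal(nrow(p1), 160)
  expect_true(all(p1$points == 5L))
  # part 1: colors of interest, control words; reward follows the color
  expect_true(all(p1$color %in% c("yellow", "green", "red", "blue")))
  expect_true(all(p1$word %in% c("white", "orange", "brown", "pink")))
  expect_true(all((p1$color %in% m$cn_colors) == (p1$rewarded_task == "CN")))
  # part 2: control colors, words of interest; reward follows the word
  expect_true(all(p2$color %in% c("white", "orange", "brown", "pink")))
  expect_true(all((p2$word %in% m$cn_words) == (p2$rewarded_task == "CN")))
  # exact balance of unique stimuli
  expect_true(all(table(paste(p1$color, p1$word)) == 10))
  expect_true(all(table(paste(p2$color, p2$word)) == 10))
  expect_error(generate_mapping_phase(m, 1, 150), "divisible")
})

test_that("transfer composition matches the frequency manipulation exactly", {
  expect_equal(
    transfer_composition(50, 200),
    c(EITHER_COLOR = 50, EITHER_WORD = 50, BOTH = 40, NEITHER = 20,
      WR_CONTROL = 40, CN_CONTROL = 0))
  expect_equal(
    transfer_composition(0, 200),
    c(EITHER_COLOR = 0, EITHER_WORD = 0, BOTH = 40, NEITHER = 20,
      WR_CONTROL = 40, CN_CONTROL = 100))
  expect_equal(unname(transfer_composition(20, 200)[c("BOTH", "CN_CONTROL")]),
               c(40, 60))
  expect_error(transfer_composition(20, 125), "integer")
  expect_error(transfer_composition(35), "group")
})

test_that("transfer phase satisfies design invariants in all groups", {
  m <- build_feature_mapping()
  map_stim <- c(
    paste(generate_mapping_phase(m, 1, 160, 1)$color,
          generate_mapping_phase(m, 1, 160, 1)$word),
    paste(generate_mapping_phase(m, 2, 160, 1)$color,
          generate_mapping_phase(m, 2, 160, 1)$word))
  for (g in c(0, 20, 50)) {
    tr <- generate_transfer_phase(m, g, 200, seed = g + 5)
    expect_equal(nrow(tr), 200)
    expect_true(all(tr$points == 10L))
    cnt <- table(tr$trial_type)
    comp <- transfer_composition(g, 200)
    expect_equal(as.vector(cnt[names(comp)[comp > 0]]),
                 unname(comp[comp > 0]))
    # CN rewarded on exactly half of transfer trials
    expect_equal(sum(tr$rewarded_task == "CN"), 100)
    # never congruent; never seen during mapping
    expect_true(all(tr$color != tr$word))
    expect_false(any(paste(tr$color, tr$word) %in% map_stim))
    # rewarded task per trial type
    expect_true(all(tr$rewarded_task[tr$trial_type %in%
      c("BOTH", "NEITHER", "WR_CONTROL")] == "WR"))
    expect_true(all(tr$rewarded_task[tr$trial_type %in%
      c("EITHER_COLOR", "EITHER_WORD", "CN_CONTROL")] == "CN"))
    # balanced presentation of unique stimuli within each type: exact when
    # the trial count divides the stimulus count, off by one otherwise
    for (ty in names(cnt)) {
      stim_cnt <- table(paste(tr$color, tr$word)[tr$trial_type == ty])
      if (cnt[[ty]] %% length(stim_cnt) == 0) {
        expect_equal(max(stim_cnt), min(stim_cnt))
      } else {
        expect_lte(max(stim_cnt) - min(stim_cnt), 1)
      }
    }
  }
})

test_that("full experiment has 520 trials and fixed phase order", {
  sched <- generate_experiment(3, group = "balanced", seed = 2)
  expect_equal(as.vector(table(sched$participant)), rep(520L, 3))
  expect_setequal(unique(sched$group), c(0L, 20L, 50L))
  one <- sched[sched$participant == 1, ]
  expect_identical(unique(one$phase), c("mapping1", "mapping2", "transfer"))
  expect_equal(one$trial_index, 1:520)
  expect_true(all(one$color != one$word))
  # reproducible under the master seed
  expect_identical(sched, generate_experiment(3, group = "balanced", seed = 2))
})

test_that("rewards are points for the rewarded task and zero otherwise", {
  trials <- data.frame(
    trial_type = c("BOTH", "EITHER_COLOR", "MAPPING_CN"),
    rewarded_task = c("WR", "CN", "CN"),
    points = c(10L, 10L, 5L))
  expect_equal(reward_for_response(trials, c("CN", "CN", "CN")),
               c(0L, 10L, 5L))
  expect_equal(reward_for_response(trials, "WR"), c(10L, 0L, 0L))
})

test_that("schedules round-trip through the delimited text format", {
  sched <- generate_experiment(1, group = 20, seed = 8)
  path <- tempfile(fileext = ".tsv")
  write_schedule(sched, path)
  back <- read_schedule(path)
  expect_equal(back, sched)
})
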