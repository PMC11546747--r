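# Operant task structures: PR ratios, demand prices, session simulation,
# go/no-go plans.

test_that("PR requirement sequence reproduces the printed ratios and extends by rule", {
  printed <- c(1L, 2L, 4L, 6L, 9L, 12L, 15L, 20L, 25L, 32L, 40L, 50L,
               62L, 77L, 95L, 118L)
  expect_identical(prRequirementSequence(16), printed)
  # the generating rule agrees with the printed list on every index
  rule <- as.integer(floor(5 * exp(0.2 * (1:16)) + 0.5) - 5)
  expect_identical(rule, printed)
  expect_identical(prRequirementSequence(8)[8], 20L)
  expect_identical(prRequirementSequence(17)[17], 145L)
  expect_error(prRequirementSequence(0), "n_trials")
  expect_error(prRequirementSequence(c(2, 3)), "n_trials")
})

test_that("demand price schedules are emitted exactly", {
  expect_identical(demandPriceSchedule("food_demand"),
                   c(180L, 90L, 45L, 15L, 5L))
  expect_identical(demandPriceSchedule("remi_demand"),
                   c(6L, 10L, 16L, 25L, 40L, 63L, 100L, 158L))
  expect_error(demandPriceSchedule("banana_demand"), "unknown")
})

test_that("schedule specs enforce their structural invariants", {
  sp <- scheduleSpec("food_PR")
  expect_s3_class(sp, "ScheduleSpec")
  expect_identical(sp$ratio_progression[1:16], prRequirementSequence(16))
  expect_error(scheduleSpec("food_PR", ratio_progression = c(5, 3, 1)),
               "non-decreasing")
  expect_error(scheduleSpec("food_demand", ratio_progression = c(5, 15, 45)),
               "decreasing")
  expect_error(scheduleSpec("food_FR", ratio_progression = c(5, 0)),
               "positive")
  expect_error(scheduleSpec("food_PR", session_length = -1), "session_length")
})

test_that("PR simulation respects the ratio progression and the 10-min rule", {
  sched <- scheduleSpec("food_PR")
  # no pressing: zero rewards, session ends at exactly 600 s
  ev0 <- simulatePRSession(list(press_rate = 0), sched, seed = 1)
  tab <- eventTable(ev0)
  expect_identical(sum(tab$event == "reward"), 0L)
  expect_equal(max(tab$time_s), 600)

  ev <- simulatePRSession(list(press_rate = 1.5, persistence_limit = 120),
                          sched, seed = 4)
  tab <- eventTable(ev)
  # cumulative presses at each reward equal the running ratio sum
  rew_tr <- tab$trial_index[tab$event == "reward"]
  for (tr in rew_tr) {
    presses_before <- sum(tab$event == "active_press" &
                            tab$time_s <= tab$time_s[tab$event == "reward" &
                                                       tab$trial_index == tr])
    expect_identical(presses_before, sum(prRequirementSequence(tr)))
  }
  # per-trial presses equal that trial's requirement on rewarded trials
  for (tr in rew_tr) {
    expect_identical(sum(tab$event == "active_press" & tab$trial_index == tr),
                     prRequirementSequence(tr)[tr])
  }
  # persistence quit: last trial's requirement exceeds the limit
  expect_gt(prRequirementSequence(max(tab$trial_index))[max(tab$trial_index)],
            120)
})

test_that("PR simulation is bit-identical under the same seed", {
  sched <- scheduleSpec("remi_PR")
  a <- simulatePRSession(list(press_rate = 1, persistence_limit = 50),
                         sched, seed = 42)
  b <- simulatePRSession(list(press_rate = 1, persistence_limit = 50),
                         sched, seed = 42)
  expect_identical(eventTable(a), eventTable(b))
  expect_true("infusion" %in% eventTable(a)$event)  # drug task codes infusions
  expect_error(simulatePRSession(list(press_rate = -1), sched, seed = 1),
               "non-negative")
  expect_error(simulatePRSession(list(press_rate = 1),
                                 scheduleSpec("food_FR"), seed = 1),
               "PR")
})

test_that("go/no-go plans are 64 trials, 32/32, in blocks of 10-11", {
  for (seed in 1:25) {
    plan <- goNogoSessionPlan(phase = 1, seed = seed)
    expect_length(plan$trial_types, 64L)
    expect_identical(sum(plan$trial_types == "go"), 32L)
    expect_identical(sum(plan$trial_types == "nogo"), 32L)
    expect_true(all(plan$block_sizes %in% c(10L, 11L)))
    expect_identical(sum(plan$block_sizes), 64L)
  }
  expect_equal(goNogoSessionPlan(1, 1)$cue_duration_nogo, 5)
  expect_equal(goNogoSessionPlan(2, 1)$cue_duration_nogo, 10)
  expect_equal(goNogoSessionPlan(2, 1)$cue_duration_go, 5)
  expect_error(goNogoSessionPlan(3, 1), "phase")
  # per-block class quotas are near-balanced (5 or 6 per class)
  plan <- goNogoSessionPlan(1, 9)
  idx <- cumsum(c(0, plan$block_sizes))
  for (b in seq_along(plan$block_sizes)) {
    blk <- plan$trial_types[(idx[b] + 1):idx[b + 1]]
    expect_true(sum(blk == "go") %in% 5:6)
  }
})

test_that("TrialEvents validity catches malformed streams", {
  expect_error(new("TrialEvents",
                   events = data.frame(time_s = c(2, 1), event = "cue_on",
                                       trial_index = 1:2)),
               "non-decreasing")
  expect_error(new("TrialEvents",
                   events = data.frame(time_s = 1, event = "warp_drive",
                                       trial_index = 1L)),
               "unknown event")
  expect_error(new("TrialEvents",
                   events = data.frame(time_s = 1:2, event = "cue_on",
                                       trial_index = c(1L, 3L))),
               "contiguous")
})
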