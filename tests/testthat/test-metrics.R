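test_that("binned accuracy partitions pokes into 30-min bins", {
  sp <- scheduleSpec("FR", ratio = 5, sessionDurationS = 10800)
  # all-target log: 1.0 overall and in every occupied bin
  log <- pokeLog(rep("poke_left", 40), sp, times = seq(10, 400, 10))
  acc <- binnedAccuracy(log)
  expect_identical(acc$overall, 1)
  expect_identical(length(acc$bins), 6L)  # 3-h session, 6 x 30-min bins
  expect_identical(acc$bins[1], 1)
  expect_true(all(is.na(acc$bins[-1])))  # empty bins carry absent values

  # constructed per-bin counts: bin1 3/4 target, bin2 1/3, bin3 empty
  kinds <- c("poke_left", "poke_left", "poke_right", "poke_left",
             "poke_left", "poke_right", "poke_right")
  times <- c(100, 500, 900, 1700, 1900, 2500, 3500)
  log <- pokeLog(kinds, sp, times = times)
  acc <- binnedAccuracy(log)
  expect_equal(acc$bins[1:2], c(3 / 4, 1 / 3))
  expect_identical(acc$binCounts[1:3], c(4L, 3L, 0L))
  # conservation and poke-weighted-mean identity
  expect_identical(sum(acc$binCounts), 7L)
  occ <- acc$binCounts > 0
  expect_equal(acc$overall,
               sum(acc$bins[occ] * acc$binCounts[occ]) / sum(acc$binCounts))

  empty <- pokeLog(character(0), sp, times = numeric(0))
  expect_identical(binnedAccuracy(empty)$overall, NA_real_)
})

test_that("criterion detection matches its definition and the oracle", {
  sp <- scheduleSpec("FR", ratio = 5, sessionDurationS = 2000)
  # 80 consecutive targets reach criterion at poke 80
  cr <- detectCriterion(pokeLog(rep("poke_left", 120), sp))
  expect_true(cr@reached)
  expect_identical(cr@pokeIndex, 80L)
  expect_identical(cr@targetPokes, 80L)
  expect_identical(cr@nontargetPokes, 0L)
  expect_identical(cr@timeToCriterionS, 79)  # pokes at 1 Hz from t = 1

  # strict alternation caps the window at 50/100: never reached
  alt <- pokeLog(rep(c("poke_left", "poke_right"), 300),
                 scheduleSpec("FR", ratio = 5, sessionDurationS = 601))
  expect_false(detectCriterion(alt)@reached)

  # random logs vs the exhaustive-window oracle
  withr::with_seed(17, {
    for (i in 1:50) {
      log <- randomPokeLog(500, pTarget = runif(1, 0.6, 0.95))
      target <- events(log)$kind == "poke_left"
      got <- detectCriterion(log)
      want <- bruteCriterion(target)
      if (is.na(want)) expect_false(got@reached)
      else expect_identical(got@pokeIndex, want)
    }
  })
  expect_error(detectCriterion(alt, window = 10, threshold = 20),
               "window")
})

test_that("latencies derive from their defining events or stay absent", {
  sp <- scheduleSpec("FR", ratio = 5, sessionDurationS = 10800)
  log <- pokeLog(c("poke_right", rep("poke_left", 5), "pellet_dispensed"),
                 sp, times = c(120, 10:14 + 125, 139))
  lat <- latencyProfile(log)
  expect_identical(lat$firstPokeLatencyS, 120)
  expect_identical(lat$targetPokeLatencyS, 135)
  expect_identical(lat$firstPelletLatencyS, 19)
  expect_identical(lat$sessionDurationS, 19)

  # FR5 at 1 Hz from t = 10: first pellet 4 s after the first poke
  log <- runDevice(sp, data.frame(timestamp = 10:14, kind = "poke_left"))
  expect_identical(latencyProfile(log)$firstPelletLatencyS, 4)

  lat0 <- latencyProfile(pokeLog(character(0), sp, times = numeric(0)))
  expect_true(all(is.na(unlist(lat0))))
})

test_that("reward efficiency counts non-target pokes per pellet", {
  sp <- scheduleSpec("FR", ratio = 2, sessionDurationS = 3600)
  stream <- data.frame(
    timestamp = 1:20,
    kind = rep(c("poke_left", "poke_left", "poke_right"), length.out = 20))
  log <- runDevice(sp, stream)
  eff <- rewardEfficiency(log)
  manualPellets <- sum(stream$kind == "poke_left") %/% 2L
  expect_identical(eff$pellets, manualPellets)
  expect_equal(eff$nontargetPerPellet,
               sum(stream$kind == "poke_right") / manualPellets)

  none <- rewardEfficiency(pokeLog(rep("poke_right", 10), sp))
  expect_true(none$noPellets)
  expect_identical(none$nontargetPerPellet, NA_real_)
})

test_that("breakpoints honour the 10-min inactivity rule", {
  pr <- scheduleSpec("PR", sessionDurationS = 10800)
  # complete requirements 1, 2, 4 (7 pokes), 11-min silence, then poking on
  stream <- data.frame(timestamp = c(1:7, 700:705), kind = "poke_left")
  bp <- breakpointMetrics(runDevice(pr, stream))
  expect_identical(bp$breakpoint, 4L)
  expect_identical(bp$resets, 0L)

  # no gap >= 10 min: requirement of the final pellet of the session
  bp2 <- breakpointMetrics(runDevice(pr, data.frame(timestamp = 1:13,
                                                    kind = "poke_left")))
  expect_identical(bp2$breakpoint, 6L)  # 1+2+4+6 = 13 pokes

  # no pellets: breakpoint 0, flagged
  bp3 <- breakpointMetrics(runDevice(pr, data.frame(timestamp = 1,
                                                    kind = "poke_right")))
  expect_identical(bp3$breakpoint, 0L)
  expect_true(bp3$noPellets)

  expect_error(breakpointMetrics(pokeLog("poke_left",
                                         scheduleSpec("FR", ratio = 1))),
               "PR")
})

test_that("re-setting PR logs yield reset counts and post-reset pokes", {
  rpr <- scheduleSpec("RPR", sessionDurationS = 10800)
  # segment 1: reqs 1, 2 done (3 pokes); reset; segment 2: req 1 done, one
  # poke toward req 2, non-target poke; reset; segment 3: two target pokes
  times <- c(1, 2, 3, 700, 701, 702, 1400, 1401)
  kinds <- c(rep("poke_left", 5), "poke_right", "poke_left", "poke_left")
  log <- runDevice(rpr, data.frame(timestamp = times, kind = kinds))
  bp <- breakpointMetrics(log)
  expect_identical(bp$resets, 2L)
  # pokes from the first reset marker (t = 700) onward: 4 target, 1 non
  expect_identical(bp$postResetTarget, 4L)
  expect_identical(bp$postResetNontarget, 1L)
  # breakpoint: last pellet before the first >=10-min gap (req 2 at t = 3)
  expect_identical(bp$breakpoint, 2L)
})

test_that("scoring ignores pellet-retrieval events", {
  sp <- scheduleSpec("FR", ratio = 2, sessionDurationS = 3600)
  stream <- data.frame(timestamp = 1:12,
                       kind = rep(c("poke_left", "poke_right"),
                                  length.out = 12))
  plain <- runDevice(sp, stream)
  ev <- events(plain)
  pel <- ev$timestamp[ev$kind == "pellet_dispensed"]
  withRet <- eventLog(
    rbind(ev, data.frame(timestamp = pel + 0.5, kind = "pellet_removed",
                         requirement = NA_integer_))[
      order(c(ev$timestamp, pel + 0.5)), ],
    sp)
  a <- scoreSession(plain); b <- scoreSession(withRet)
  cols <- setdiff(names(a), "session_id")
  expect_equal(a[cols], b[cols])
})
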