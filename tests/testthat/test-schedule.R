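test_that("progressive-ratio requirements follow the exponential formula", {
  pr <- scheduleSpec("PR")
  expect_identical(vapply(1:6, function(n) requiredPokes(pr, n),
                          integer(1)),
                   c(1L, 2L, 4L, 6L, 9L, 12L))
  reqs <- vapply(1:30, function(n) requiredPokes(pr, n), integer(1))
  expect_true(all(diff(reqs) >= 0))
  expect_identical(requiredPokes(pr, 1), 1L)  # floor at 1
  expect_error(requiredPokes(pr, 0), "positive")
})

test_that("fixed, variable and no-requirement schedules answer correctly", {
  expect_identical(requiredPokes(scheduleSpec("FR", ratio = 5), 99), 5L)
  expect_identical(requiredPokes(scheduleSpec("EXT"), 1), NA_integer_)
  expect_identical(requiredPokes(scheduleSpec("FREE"), 1), NA_integer_)
  vr <- scheduleSpec("VR", rangeLow = 1, rangeHigh = 5)
  draws <- withr::with_seed(7, vapply(rep(1, 2e4),
                                      function(n) requiredPokes(vr, n),
                                      integer(1)))
  expect_true(all(draws %in% 1:5))
  expect_gt(chisq.test(tabulate(draws, 5))$p.value, 0.01)
})

test_that("device transitions implement ratio, extinction and free feeding", {
  fr1 <- scheduleSpec("FR", ratio = 1)
  out <- advanceDevice(newDeviceState(fr1), fr1, 1, "poke_left")
  expect_identical(out$emitted$kind, "pellet_dispensed")

  # 4 target, 1 non-target, 1 target on FR5: pellet on the 5th target poke
  fr5 <- scheduleSpec("FR", ratio = 5)
  st <- newDeviceState(fr5)
  kinds <- c(rep("poke_left", 4), "poke_right", "poke_left")
  pellets <- 0L
  for (i in seq_along(kinds)) {
    out <- advanceDevice(st, fr5, i, kinds[i])
    st <- out$state
    pellets <- pellets + nrow(out$emitted)
    if (i < 6) expect_identical(pellets, 0L) else expect_identical(pellets, 1L)
  }

  ext <- scheduleSpec("EXT")
  st <- newDeviceState(ext)
  got <- 0L
  for (i in 1:100) {
    out <- advanceDevice(st, ext, i, "poke_left")
    st <- out$state
    got <- got + nrow(out$emitted)
  }
  expect_identical(got, 0L)

  free <- scheduleSpec("FREE")
  st <- newDeviceState(free)
  out <- advanceDevice(st, free, 5, "poke_left")
  expect_identical(nrow(out$emitted), 0L)  # pokes have no effect
  out <- advanceDevice(out$state, free, 10, "pellet_removed")
  expect_identical(out$emitted$kind, "pellet_dispensed")

  fr <- scheduleSpec("FR", ratio = 2)
  expect_error(advanceDevice(newDeviceState(fr), fr, 1, "pellet_removed"),
               "no pellet")
})

test_that("re-setting PR drops to requirement 1 after the inactivity window", {
  rpr <- scheduleSpec("RPR", inactivityResetS = 600)
  st <- newDeviceState(rpr)
  t <- 0
  # earn pellets at requirements 1, 2, 4, 6 -> at requirement 9
  for (i in 1:13) {
    t <- t + 1
    st <- advanceDevice(st, rpr, t, "poke_left")$state
  }
  expect_identical(st@currentRequirement, 9L)
  # 11-minute silence, then a target poke: requirement back at 1, reset
  out <- advanceDevice(st, rpr, t + 660, "poke_left")
  expect_identical(out$state@resets, 1L)
  expect_identical(out$emitted$requirement, 1L)  # poke completed req 1
})

test_that("reversal swaps the target side and is an involution", {
  sp <- scheduleSpec("FR", ratio = 5, targetSide = "left")
  expect_identical(applyReversal(sp)@targetSide, "right")
  expect_identical(applyReversal(applyReversal(sp)), sp)
  # after reversal, left pokes are non-target
  stream <- data.frame(timestamp = 1:10, kind = "poke_left")
  log <- runDevice(applyReversal(sp), stream)
  expect_identical(sum(events(log)$kind == "pellet_dispensed"), 0L)
  expect_identical(binnedAccuracy(log)$overall, 0)
})

test_that("FR conservation holds on arbitrary interleaved streams", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- sample(3:7, 1)
      spec <- scheduleSpec("FR", ratio = n, sessionDurationS = 3000)
      kinds <- sample(c("poke_left", "poke_right"), 800, replace = TRUE,
                      prob = c(0.6, 0.4))
      stream <- data.frame(timestamp = sort(runif(800, 0, 2999)),
                           kind = kinds)
      log <- runDevice(spec, stream)
      targets <- sum(kinds == "poke_left")
      expect_identical(sum(events(log)$kind == "pellet_dispensed"),
                       as.integer(targets %/% n))
    })
  }
})

test_that("RPR with an infinite reset window is event-identical to PR", {
  stream <- withr::with_seed(99,
    data.frame(timestamp = sort(runif(500, 0, 10000)),
               kind = sample(c("poke_left", "poke_right"), 500,
                             replace = TRUE)))
  pr <- runDevice(scheduleSpec("PR"), stream)
  rpr <- runDevice(scheduleSpec("RPR", inactivityResetS = Inf), stream)
  expect_identical(events(pr), events(rpr))
})

test_that("the non-ratchet dialect resets progress on non-target pokes", {
  fr3 <- scheduleSpec("FR", ratio = 3)
  kinds <- c("poke_left", "poke_left", "poke_right", "poke_left")
  stream <- data.frame(timestamp = 1:4, kind = kinds)
  expect_identical(
    sum(events(runDevice(fr3, stream, ratchet = TRUE))$kind ==
          "pellet_dispensed"), 1L)
  expect_identical(
    sum(events(runDevice(fr3, stream, ratchet = FALSE))$kind ==
          "pellet_dispensed"), 0L)
})

test_that("runDevice handles empty streams and counts completions", {
  sp <- scheduleSpec("FR", ratio = 5)
  expect_identical(length(runDevice(sp, data.frame(timestamp = numeric(0),
                                                   kind = character(0)))),
                   0L)
  stream <- data.frame(timestamp = 1:25, kind = "poke_left")
  expect_identical(sum(events(runDevice(sp, stream))$kind ==
                         "pellet_dispensed"), 5L)
})
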