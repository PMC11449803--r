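test_that("softmax choice probabilities follow the logistic policy", {
  expect_identical(pokeLeftProb(c(0.3, 0.9), NA, agentParams(beta = 0,
                                                             kappa = 0)),
                   0.5)
  expect_equal(pokeLeftProb(c(0.6, 0.4), NA, agentParams(beta = 2,
                                                         kappa = 0)),
               plogis(2 * 0.2))  # ~0.599
  expect_gt(pokeLeftProb(c(1, 0), NA, agentParams(beta = 50)), 1 - 1e-10)
  # perseveration raises the probability of repeating the last side
  p <- agentParams(beta = 1, kappa = 0.5)
  expect_gt(pokeLeftProb(c(0, 0), "left", p), 0.5)
  expect_lt(pokeLeftProb(c(0, 0), "right", p), 0.5)
})

test_that("delta-rule updates are asymmetric and leave the other value", {
  p <- agentParams(alphaPos = 0.5, alphaNeg = 0.3)
  expect_equal(updateValues(c(0, 0), "left", "reward", p), c(0.5, 0))
  expect_equal(updateValues(c(0.5, 0.2), "left", "no_reward", p),
               c(0.35, 0.2))
  p0 <- agentParams(alphaNeg = 0)
  expect_identical(updateValues(c(0.4, 0.1), "right", "no_reward", p0),
                   c(0.4, 0.1))
})

test_that("session simulation is deterministic and passes log validation", {
  specs <- list(scheduleSpec("FR", ratio = 5, sessionDurationS = 900),
                scheduleSpec("VR", rangeLow = 1, rangeHigh = 5,
                             sessionDurationS = 900),
                scheduleSpec("RPR", sessionDurationS = 900),
                scheduleSpec("EXT", sessionDurationS = 900),
                scheduleSpec("FREE", sessionDurationS = 900))
  for (sp in specs) {
    a <- simulateSession(agentParams(), sp, seed = 11)
    b <- simulateSession(agentParams(), sp, seed = 11)
    expect_identical(events(a), events(b))
    expect_true(validObject(a))
  }
  c <- simulateSession(agentParams(), specs[[1]], seed = 12)
  expect_false(identical(events(simulateSession(agentParams(), specs[[1]],
                                                seed = 11)),
                         events(c)))
})

test_that("deterministic and random choice limits behave as expected", {
  # near-greedy agent with values favouring the target: perfect accuracy
  sharp <- agentParams(beta = 100, alphaPos = 0, alphaNeg = 0,
                       qInit = c(1, 0), pauseHazard = 0)
  log <- simulateSession(sharp, scheduleSpec("FR", ratio = 5,
                                             sessionDurationS = 3600),
                         seed = 21)
  sc <- scoreSession(log)
  expect_identical(sc$accuracy_overall, 1)
  expect_identical(sc$pellets, sc$target_pokes %/% 5L)

  # indifferent agent: accuracy within exact binomial 99% bounds of 0.5
  flat <- agentParams(beta = 0, kappa = 0, ipiMu = log(1.5), ipiSigma = 0.3,
                      pauseHazard = 0)
  log <- simulateSession(flat, scheduleSpec("FR", ratio = 5,
                                            sessionDurationS = 7200),
                         seed = 22)
  ev <- events(log)
  n <- sum(ev$kind %in% c("poke_left", "poke_right"))
  expect_gt(n, 2000)
  hits <- sum(ev$kind == "poke_left")
  bounds <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})

test_that("cohorts are reproducible and sized by the design", {
  fr1 <- scheduleSpec("FR", ratio = 1, sessionDurationS = 600)
  design <- cohortDesign(
    list(list(label = "a", params = agentParams(), n = 3),
         list(label = "b", params = agentParams(kappa = 0.6), n = 3)),
    list(list(spec = fr1, nSessions = 3),
         list(spec = fr1, nSessions = 1, reverse = TRUE)),
    masterSeed = 5)
  co <- simulateCohort(design)
  expect_identical(length(co), 6L)
  expect_identical(unname(vapply(co, function(s) length(s$logs),
                                 integer(1))),
                   rep(4L, 6))
  co2 <- simulateCohort(design)
  expect_identical(lapply(co, function(s) lapply(s$logs, events)),
                   lapply(co2, function(s) lapply(s$logs, events)))
  design@masterSeed <- 6L
  co3 <- simulateCohort(design)
  expect_false(identical(events(co$a_01$logs[[1]]),
                         events(co3$a_01$logs[[1]])))
  # reversal stage flips the target side
  expect_identical(co$a_01$logs$stage1_session1@schedule@targetSide, "left")
  expect_identical(co$a_01$logs$stage2_session1@schedule@targetSide,
                   "right")
})

test_that("faster negative-feedback learning speeds reversal adaptation", {
  mk <- function(aNeg, kap, label, seed) {
    p <- agentParams(alphaPos = 0.35, alphaNeg = aNeg, beta = 3,
                     kappa = kap, ipiMu = log(4), ipiSigma = 0.6,
                     pauseHazard = 0.02)
    fr1 <- scheduleSpec("FR", ratio = 1, sessionDurationS = 3600)
    cohortDesign(list(list(label = label, params = p, n = 12)),
                 list(list(spec = fr1, nSessions = 2),
                      list(spec = fr1, nSessions = 1, reverse = TRUE)),
                 masterSeed = seed)
  }
  revNT <- function(cohort) vapply(cohort, function(s) {
    cr <- detectCriterion(s$logs[["stage2_session1"]])
    if (cr@reached) as.numeric(cr@nontargetPokes) else NA_real_
  }, numeric(1))
  ctrl <- revNT(simulateCohort(mk(0.1, 0.5, "control", 31)))
  trt <- revNT(simulateCohort(mk(0.4, 0.1, "treated", 32)))
  expect_lt(median(trt, na.rm = TRUE), median(ctrl, na.rm = TRUE))
})

test_that("maximum-likelihood refit converges near generating values", {
  gen <- agentParams(alphaPos = 0.4, alphaNeg = 0.15, beta = 3,
                     kappa = 0.3, ipiMu = log(3), ipiSigma = 0.5,
                     pauseHazard = 0.01)
  fr1 <- scheduleSpec("FR", ratio = 1, sessionDurationS = 1800)
  fr3 <- scheduleSpec("FR", ratio = 3, sessionDurationS = 1800)
  logs <- lapply(1:10, function(i) {
    sp <- if (i %% 2) fr1 else fr3  # mixed schedules pin the value scale
    simulateSession(gen, if ((i %/% 2) %% 2) applyReversal(sp) else sp,
                    seed = 500 + i)
  })
  fit <- fitAgentParams(logs, kappa = 0.3)
  expect_identical(fit$convergence, 0L)
  expect_lt(abs(fit$alphaPos - 0.4) / 0.4, 0.5)
  expect_lt(abs(fit$alphaNeg - 0.15) / 0.15, 0.5)
  expect_lt(abs(fit$beta - 3) / 3, 0.5)
})
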