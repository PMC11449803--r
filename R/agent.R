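#' @include schedule.R
NULL

#' Softmax choice probability and draw
#'
#' `pokeLeftProb()` returns the probability that the agent pokes left:
#' \deqn{P(\mathrm{left}) = \mathrm{logistic}(\beta (Q_L - Q_R) +
#'   \kappa [last = L] - \kappa [last = R])}
#' `chooseAction()` draws a side from that probability using R's RNG.
#'
#' @param values numeric length-2 action values (left, right), finite.
#' @param lastAction `"left"`, `"right"` or `NA` (no previous poke).
#' @param params an [AgentParams-class].
#' @return `pokeLeftProb()`: probability in \[0, 1\]; `chooseAction()`:
#'   `"left"` or `"right"`.
#' @examples
#' p <- agentParams(beta = 2, kappa = 0)
#' pokeLeftProb(c(0.6, 0.4), NA, p)  # ~0.599
#' @export
pokeLeftProb <- function(values, lastAction, params) {
  stopifnot(is(params, "AgentParams"), all(is.finite(values)))
  bias <- if (is.na(lastAction)) 0
          else if (lastAction == "left") params@kappa else -params@kappa
  plogis(params@beta * (values[1] - values[2]) + bias)
}

#' @rdname pokeLeftProb
#' @export
chooseAction <- function(values, lastAction, params) {
  if (runif(1) < pokeLeftProb(values, lastAction, params)) "left" else "right"
}

#' Delta-rule value update with asymmetric learning rates
#'
#' Updates the chosen action's value toward the outcome,
#' `Q <- Q + alpha * (r - Q)`, using `alphaPos` when the poke was rewarded
#' (`r = 1`) and `alphaNeg` when it was not (`r = 0`). The unchosen value
#' is unchanged.
#'
#' @param values numeric length-2 action values (left, right).
#' @param action `"left"` or `"right"`.
#' @param outcome `"reward"` or `"no_reward"`.
#' @param params an [AgentParams-class].
#' @return Updated length-2 values.
#' @examples
#' updateValues(c(0, 0), "left", "reward", agentParams(alphaPos = 0.5))
#' @export
updateValues <- function(values, action, outcome, params) {
  stopifnot(is(params, "AgentParams"),
            action %in% SIDES, outcome %in% c("reward", "no_reward"))
  i <- if (action == "left") 1L else 2L
  r <- as.numeric(outcome == "reward")
  alpha <- if (r > 0) params@alphaPos else params@alphaNeg
  values[i] <- values[i] + alpha * (r - values[i])
  values
}

# Core simulator: returns list(log=EventLog, qFinal=values). Timestamps are
# quantised to the device's 0.1 s logging resolution.
.simulateSessionCore <- function(params, spec, qInit, sessionId, subjectId,
                                 group) {
  dur <- spec@sessionDurationS
  state <- .initialState(spec)
  Q <- qInit
  last <- NA_character_
  bp <- params@beta; kp <- params@kappa
  aPos <- params@alphaPos; aNeg <- params@alphaNeg
  hasReq <- !spec@kind %in% c("EXT", "FREE")

  cap <- 1024L
  ts <- numeric(cap); kd <- character(cap); rq <- integer(cap); m <- 0L
  push <- function(t, k, r) {
    if (m == cap) {
      cap <<- cap * 2L
      length(ts) <<- cap; length(kd) <<- cap; length(rq) <<- cap
    }
    m <<- m + 1L
    ts[m] <<- t; kd[m] <<- k; rq[m] <<- r
  }
  remT <- numeric(0)  # pending pellet retrievals

  if (identical(spec@kind, "FREE")) {
    # magazine training: retrieval chain, pellet re-dispensed on removal
    push(0, "pellet_dispensed", NA_integer_)
    t <- 0
    repeat {
      t <- t + rexp(1, 1 / params@retrievalMu) +
        rlnorm(1, params@ipiMu, params@ipiSigma)
      t <- round(t, 1)
      if (t > dur) break
      push(t, "pellet_removed", NA_integer_)
      push(t, "pellet_dispensed", NA_integer_)
    }
    ev <- data.frame(timestamp = ts[seq_len(m)], kind = kd[seq_len(m)],
                     requirement = rq[seq_len(m)], stringsAsFactors = FALSE)
    return(list(log = eventLog(ev, spec, sessionId, subjectId, group),
                qFinal = Q))
  }

  t <- 0
  repeat {
    gap <- rlnorm(1, params@ipiMu, params@ipiSigma)
    if (runif(1) < params@pauseHazard)
      gap <- gap + rlnorm(1, params@pauseMu, params@pauseSigma)
    t <- round(t + gap, 1)
    if (t > dur) break
    pl <- plogis(bp * (Q[1] - Q[2]) +
                   (if (is.na(last)) 0 else if (last == "left") kp else -kp))
    side <- if (runif(1) < pl) "left" else "right"
    kind <- if (side == "left") "poke_left" else "poke_right"
    res <- .advance(state, spec, t, kind, ratchet = TRUE)
    reqInForce <- if (res$reward) res$emitted$requirement[1]
                  else res$state$currentRequirement
    push(t, kind, if (hasReq) reqInForce else NA_integer_)
    if (res$reward) {
      push(t, "pellet_dispensed", res$emitted$requirement[1])
      remT <- c(remT, round(t + rexp(1, 1 / params@retrievalMu), 1))
      i <- if (side == "left") 1L else 2L
      Q[i] <- Q[i] + aPos * (1 - Q[i])
    } else {
      # per-poke negative feedback on every non-dispensing poke
      i <- if (side == "left") 1L else 2L
      Q[i] <- Q[i] + aNeg * (0 - Q[i])
    }
    state <- res$state
    last <- side
  }

  ev <- data.frame(timestamp = ts[seq_len(m)], kind = kd[seq_len(m)],
                   requirement = rq[seq_len(m)], stringsAsFactors = FALSE)
  remT <- remT[remT <= dur]
  if (length(remT)) {
    rem <- data.frame(timestamp = remT, kind = "pellet_removed",
                      requirement = NA_integer_, stringsAsFactors = FALSE)
    ev <- rbind(ev, rem)
    # stable sort: pokes/dispenses precede a removal at the same timestamp
    ev <- ev[order(ev$timestamp), , drop = FALSE]
    rownames(ev) <- NULL
  }
  list(log = eventLog(ev, spec, sessionId, subjectId, group), qFinal = Q)
}

#' Simulate one operant session
#'
#' Generates a complete event log from the stochastic behaving agent: the
#' agent alternates poke bouts (log-normal inter-poke intervals) and pauses
#' (per-poke hazard, log-normal durations), chooses a side by softmax with
#' perseveration, receives reward feedback on dispensing pokes and negative
#' feedback on every other poke (delta rule, asymmetric rates), and
#' retrieves each pellet after an exponential delay. All draws come from a
#' local RNG seeded with `seed`, so identical inputs give identical logs;
#' duration draws are log-normal/exponential and therefore strictly
#' positive by construction. Timestamps are quantised to the device's
#' 0.1 s logging resolution.
#'
#' @param params an [AgentParams-class].
#' @param spec a [ScheduleSpec-class].
#' @param seed integer seed.
#' @param sessionId,subjectId,group metadata labels.
#' @param qInit optional initial action values overriding `params@qInit`
#'   (used to carry learning across sessions).
#' @return A validated [EventLog-class].
#' @examples
#' log <- simulateSession(agentParams(), scheduleSpec("FR", ratio = 5,
#'                        sessionDurationS = 600), seed = 1)
#' @export
simulateSession <- function(params, spec, seed, sessionId = "s1",
                            subjectId = "r1", group = "none",
                            qInit = params@qInit) {
  stopifnot(is(params, "AgentParams"), is(spec, "ScheduleSpec"))
  validObject(params); validObject(spec)
  withSeed(seed,
    .simulateSessionCore(params, spec, qInit, sessionId, subjectId,
                         group))$log
}

#' Simulate an operant cohort
#'
#' Runs every subject of a [CohortDesign-class] through the design's
#' protocol. Per-subject seeds are derived deterministically from the
#' master seed, so the whole cohort is reproducible from it. Action values
#' carry across sessions within a subject; a stage with `reverse = TRUE`
#' flips the target side relative to the previous stage via
#' [applyReversal()] before its sessions run.
#'
#' @param design a [CohortDesign-class].
#' @return List with one element per subject:
#'   `list(subjectId=, group=, params=, logs=)`, where `logs` is the
#'   ordered list of [EventLog-class] sessions (named
#'   `stage<i>_session<j>`).
#' @seealso [cohortDesign()], [scoreCohort()]
#' @export
simulateCohort <- function(design) {
  stopifnot(is(design, "CohortDesign"))
  validObject(design)
  out <- list()
  gi <- 0L
  for (g in design@groups) {
    if (g$n < 1) stopf("group '%s' has no subjects", g$label)
    for (s in seq_len(g$n)) {
      gi <- gi + 1L
      sid <- sprintf("%s_%02d", g$label, s)
      subjSeed <- deriveSeed(design@masterSeed, gi)
      Q <- g$params@qInit
      logs <- list()
      side <- design@protocol[[1]]$spec@targetSide
      k <- 0L
      for (si in seq_along(design@protocol)) {
        st <- design@protocol[[si]]
        spec <- st$spec
        if (st$reverse) side <- setdiff(SIDES, side)
        spec@targetSide <- side
        for (ses in seq_len(st$nSessions)) {
          k <- k + 1L
          res <- withSeed(deriveSeed(subjSeed, k),
            .simulateSessionCore(g$params, spec, Q,
                                 sessionId = sprintf("stage%d_session%d",
                                                     si, ses),
                                 subjectId = sid, group = g$label))
          Q <- res$qFinal
          logs[[sprintf("stage%d_session%d", si, ses)]] <- res$log
        }
        side <- spec@targetSide
      }
      out[[sid]] <- list(subjectId = sid, group = g$label,
                         params = g$params, logs = logs)
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Maximum-likelihood refitting
# ---------------------------------------------------------------------------

# Extract (side, outcome) sequences from a log: each poke is a choice;
# outcome 1 iff the poke dispensed a pellet (the dispense row follows the
# completing poke immediately).
.choiceSequence <- function(log) {
  ev <- log@events
  isPoke <- ev$kind %in% POKE_KINDS
  idx <- which(isPoke)
  if (!length(idx)) return(list(side = integer(0), outcome = integer(0)))
  nxt <- ev$kind[pmin(idx + 1L, nrow(ev))]
  outcome <- as.integer(idx + 1L <= nrow(ev) & nxt == "pellet_dispensed")
  side <- ifelse(ev$kind[idx] == "poke_left", 1L, 2L)
  list(side = side, outcome = outcome)
}

.agentNll <- function(aPos, aNeg, beta, kappa, qInit, seqs) {
  nll <- 0
  for (sq in seqs) {
    Q <- qInit
    last <- 0L
    side <- sq$side; outcome <- sq$outcome
    for (i in seq_along(side)) {
      bias <- if (last == 0L) 0 else if (last == 1L) kappa else -kappa
      pl <- plogis(beta * (Q[1] - Q[2]) + bias)
      p <- if (side[i] == 1L) pl else 1 - pl
      nll <- nll - log(max(p, 1e-12))
      a <- side[i]
      if (outcome[i] == 1L) Q[a] <- Q[a] + aPos * (1 - Q[a])
      else Q[a] <- Q[a] + aNeg * (0 - Q[a])
      last <- a
    }
  }
  nll
}

#' Refit agent learning parameters by maximum likelihood
#'
#' Fits `(alphaPos, alphaNeg, beta)` to the poke-by-poke choices of one or
#' more event logs by maximising the softmax-choice likelihood of the
#' asymmetric delta-rule learner, with the perseveration bonus and initial
#' values held fixed (supplied, typically at their generating values).
#' Optimisation runs on an unconstrained scale (logit for the learning
#' rates, log for beta) with `stats::optim` (BFGS).
#'
#' @param logs an [EventLog-class] or list of them (sessions are pooled).
#' @param kappa fixed perseveration bonus.
#' @param qInit fixed initial action values per session.
#' @param start optional numeric start values
#'   `c(alphaPos=, alphaNeg=, beta=)`.
#' @return Named list `alphaPos`, `alphaNeg`, `beta`, `logLik`,
#'   `convergence` (0 = converged), `nChoices`.
#' @seealso [simulateSession()]
#' @export
fitAgentParams <- function(logs, kappa = 0, qInit = c(0, 0),
                           start = c(alphaPos = 0.3, alphaNeg = 0.3,
                                     beta = 2)) {
  if (is(logs, "EventLog")) logs <- list(logs)
  seqs <- lapply(logs, .choiceSequence)
  n <- sum(vapply(seqs, function(s) length(s$side), integer(1)))
  if (n < 10L) stopf("too few pokes (%d) to fit agent parameters", n)
  obj <- function(theta) {
    .agentNll(plogis(theta[1]), plogis(theta[2]), exp(theta[3]),
              kappa, qInit, seqs)
  }
  theta0 <- c(qlogis(start[["alphaPos"]]), qlogis(start[["alphaNeg"]]),
              log(start[["beta"]]))
  fit <- optim(theta0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  list(alphaPos = plogis(fit$par[1]), alphaNeg = plogis(fit$par[2]),
       beta = exp(fit$par[3]), logLik = -fit$value,
       convergence = fit$convergence, nChoices = n)
}
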