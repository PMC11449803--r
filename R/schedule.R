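#' @include AllClasses.R
NULL

#' Response requirement for a trial
#'
#' Number of target pokes required to earn the pellet on trial `trialN`.
#' Fixed-ratio schedules return the fixed ratio; variable-ratio schedules
#' draw an i.i.d. uniform integer on `[rangeLow, rangeHigh]` from R's RNG
#' (seed upstream for reproducibility); progressive and re-setting
#' progressive schedules evaluate
#' `round(prScale * exp(prRate * trialN) - prScale)` with a floor of 1,
#' which for the default constants (rate 0.2, scale 5) yields
#' 1, 2, 4, 6, 9, 12, ... Extinction and magazine training have no
#' requirement and return `NA`.
#'
#' @param spec a [ScheduleSpec-class].
#' @param trialN positive integer trial number (numbering starts at 1).
#' @return Positive integer requirement, or `NA_integer_` for schedules
#'   with no requirement (`EXT`, `FREE`).
#' @examples
#' requiredPokes(scheduleSpec("PR"), 5)   # 9
#' requiredPokes(scheduleSpec("FR", ratio = 5), 17)  # 5
#' set.seed(1); requiredPokes(scheduleSpec("VR", rangeLow = 1, rangeHigh = 5), 1)
#' @export
requiredPokes <- function(spec, trialN) {
  stopifnot(is(spec, "ScheduleSpec"))
  if (!is.numeric(trialN) || length(trialN) != 1L || is.na(trialN) ||
      trialN < 1)
    stopf("trialN must be a positive integer (got %s)", format(trialN))
  trialN <- as.integer(trialN)
  switch(spec@kind,
    FR = spec@ratio,
    VR = as.integer(sample(seq.int(spec@rangeLow, spec@rangeHigh), 1L)),
    PR = ,
    RPR = max(1L, as.integer(round(spec@prScale * exp(spec@prRate * trialN) -
                                     spec@prScale))),
    EXT = ,
    FREE = NA_integer_)
}

#' Swap the rewarded port of a schedule
#'
#' Implements the un-cued between-session reversal: the target side is
#' swapped and every other field left unchanged. Applying it twice is the
#' identity.
#'
#' @param spec a [ScheduleSpec-class] whose kind uses a target side (all
#'   but `FREE`).
#' @return The reversed [ScheduleSpec-class].
#' @examples
#' applyReversal(scheduleSpec("FR", ratio = 5, targetSide = "left"))
#' @export
applyReversal <- function(spec) {
  stopifnot(is(spec, "ScheduleSpec"))
  spec@targetSide <- if (spec@targetSide == "left") "right" else "left"
  spec
}

# -- internal fast device state (plain list mirror of DeviceState) ----------

.initialState <- function(spec) {
  list(trialN = 1L, pokesTowardRatio = 0L,
       currentRequirement = requiredPokes(spec, 1L),
       pelletsDispensed = 0L,
       # magazine training starts with a pellet pre-loaded in the well
       pelletInWell = identical(spec@kind, "FREE"),
       lastActivityS = NA_real_, resets = 0L)
}

.stateToS4 <- function(s) {
  new("DeviceState", trialN = s$trialN,
      pokesTowardRatio = s$pokesTowardRatio,
      currentRequirement = s$currentRequirement,
      pelletsDispensed = s$pelletsDispensed, pelletInWell = s$pelletInWell,
      lastActivityS = s$lastActivityS, resets = s$resets)
}

.stateFromS4 <- function(s) {
  list(trialN = s@trialN, pokesTowardRatio = s@pokesTowardRatio,
       currentRequirement = s@currentRequirement,
       pelletsDispensed = s@pelletsDispensed, pelletInWell = s@pelletInWell,
       lastActivityS = s@lastActivityS, resets = s@resets)
}

# Core transition. `emitted` rows are (timestamp, kind, requirement).
# Returns list(state=, emitted= data.frame, reward= logical).
.advance <- function(state, spec, timestamp, kind, ratchet = TRUE) {
  emitted <- NULL
  reward <- FALSE
  isPoke <- kind %in% POKE_KINDS
  ratioKind <- spec@kind %in% c("FR", "VR", "PR", "RPR")

  if (isPoke) {
    # RPR: any 10-min (default) lapse in poking resets the schedule to 1
    # before the incoming poke is processed. Pellet removal is not activity.
    if (identical(spec@kind, "RPR") && !is.na(state$lastActivityS) &&
        is.finite(spec@inactivityResetS) &&
        timestamp - state$lastActivityS >= spec@inactivityResetS) {
      state$trialN <- 1L
      state$currentRequirement <- requiredPokes(spec, 1L)
      state$pokesTowardRatio <- 0L
      state$resets <- state$resets + 1L
    }
    state$lastActivityS <- timestamp
  }

  if (isPoke && ratioKind) {
    target <- (kind == "poke_left") == (spec@targetSide == "left")
    if (target) {
      state$pokesTowardRatio <- state$pokesTowardRatio + 1L
      if (state$pokesTowardRatio >= state$currentRequirement) {
        emitted <- data.frame(timestamp = timestamp,
                              kind = "pellet_dispensed",
                              requirement = state$currentRequirement,
                              stringsAsFactors = FALSE)
        reward <- TRUE
        state$pelletsDispensed <- state$pelletsDispensed + 1L
        state$pelletInWell <- TRUE
        state$trialN <- state$trialN + 1L
        state$pokesTowardRatio <- 0L
        state$currentRequirement <- requiredPokes(spec, state$trialN)
      }
    } else if (!ratchet) {
      state$pokesTowardRatio <- 0L
    }
  } else if (kind == "pellet_removed") {
    if (!state$pelletInWell)
      stopf("pellet_removed at t=%g with no pellet in the well", timestamp)
    if (identical(spec@kind, "FREE")) {
      # magazine training: a pellet is dispensed each time one is removed
      emitted <- data.frame(timestamp = timestamp,
                            kind = "pellet_dispensed",
                            requirement = NA_integer_,
                            stringsAsFactors = FALSE)
      state$pelletsDispensed <- state$pelletsDispensed + 1L
      state$pelletInWell <- TRUE
    } else {
      state$pelletInWell <- FALSE
    }
  }
  # pokes on EXT/FREE are logged upstream with no ratio effect
  list(state = state, emitted = emitted, reward = reward)
}

#' Create the initial device state for a schedule
#'
#' @param spec a [ScheduleSpec-class]. For `VR` schedules the first
#'   requirement is drawn from R's RNG; seed beforehand for reproducibility.
#' @return A [DeviceState-class] at trial 1 with no pokes accumulated. For
#'   magazine training (`FREE`) the well starts loaded.
#' @export
newDeviceState <- function(spec) .stateToS4(.initialState(spec))

#' Advance the device state by one event
#'
#' Applies one incoming event (a poke or a pellet removal) to the device
#' state under the given schedule and returns the new state together with
#' any emitted `pellet_dispensed` events. Target pokes increment progress
#' toward the requirement; non-target pokes are logged but (by the default
#' ratchet rule) do not change ratio progress; on completing the
#' requirement a pellet is dispensed immediately, the trial number
#' increments and a fresh requirement is drawn. Extinction never dispenses;
#' magazine training dispenses only on pellet removal. Re-setting PR resets
#' its requirement to 1 before processing a poke that follows at least
#' `inactivityResetS` seconds of poke inactivity.
#'
#' @param state a [DeviceState-class].
#' @param spec a [ScheduleSpec-class].
#' @param timestamp event time in seconds from access.
#' @param kind one of `"poke_left"`, `"poke_right"`, `"pellet_removed"`.
#' @param ratchet logical; if `FALSE`, a non-target poke resets progress
#'   toward the current requirement (dialect switch; default `TRUE`).
#' @return list with elements `state` (new [DeviceState-class]) and
#'   `emitted` (data.frame of emitted events, possibly empty).
#' @examples
#' sp <- scheduleSpec("FR", ratio = 1)
#' advanceDevice(newDeviceState(sp), sp, 1, "poke_left")$emitted
#' @export
advanceDevice <- function(state, spec, timestamp, kind, ratchet = TRUE) {
  stopifnot(is(state, "DeviceState"), is(spec, "ScheduleSpec"))
  if (!kind %in% c(POKE_KINDS, "pellet_removed"))
    stopf("cannot advance on event kind '%s'", kind)
  res <- .advance(.stateFromS4(state), spec, timestamp, kind, ratchet)
  list(state = .stateToS4(res$state), emitted = res$emitted %||% emptyEvents())
}

#' Run a poke stream through the device
#'
#' Folds [advanceDevice()] over an ordered stream of pokes and pellet
#' removals and returns the complete event log, including emitted
#' `pellet_dispensed` events (inserted immediately after the completing
#' poke, at the same timestamp) and, for magazine training, the pre-loaded
#' pellet logged at time 0.
#'
#' @param spec a [ScheduleSpec-class].
#' @param stream data.frame with columns `timestamp` (seconds, sorted) and
#'   `kind` (`poke_left`, `poke_right`, `pellet_removed`); zero rows allowed.
#' @param sessionId,subjectId,group metadata labels for the log.
#' @param ratchet see [advanceDevice()].
#' @return An [EventLog-class]. On ratio schedules the number of
#'   `pellet_dispensed` events equals the number of completed requirements.
#' @examples
#' sp <- scheduleSpec("FR", ratio = 5)
#' stream <- data.frame(timestamp = 1:25, kind = "poke_left")
#' sum(events(runDevice(sp, stream))$kind == "pellet_dispensed")  # 5
#' @export
runDevice <- function(spec, stream, sessionId = "s1", subjectId = "r1",
                      group = "none", ratchet = TRUE) {
  stopifnot(is(spec, "ScheduleSpec"))
  n <- nrow(stream)
  if (n && is.unsorted(stream$timestamp))
    stopf("poke stream must be sorted by timestamp")
  state <- .initialState(spec)
  hasReq <- !spec@kind %in% c("EXT", "FREE")

  ts <- numeric(0); kd <- character(0); rq <- integer(0)
  if (identical(spec@kind, "FREE")) {
    ts <- 0; kd <- "pellet_dispensed"; rq <- NA_integer_
  }
  if (n) {
    outT <- numeric(2L * n); outK <- character(2L * n)
    outR <- integer(2L * n); m <- 0L
    for (i in seq_len(n)) {
      kind <- stream$kind[i]; tm <- stream$timestamp[i]
      if (kind %in% POKE_KINDS) {
        # peek the RPR reset so the logged requirement is the one in force
        res <- .advance(state, spec, tm, kind, ratchet)
        # requirement in force when the poke occurred: if the poke completed
        # the ratio, .advance already drew a new one; the emitted row holds
        # the completed requirement, so recover the in-force value from it.
        reqInForce <- if (res$reward) res$emitted$requirement[1]
                      else res$state$currentRequirement
        if (!hasReq) reqInForce <- NA_integer_
        m <- m + 1L
        outT[m] <- tm; outK[m] <- kind; outR[m] <- reqInForce
        if (!is.null(res$emitted)) {
          m <- m + 1L
          outT[m] <- res$emitted$timestamp[1]
          outK[m] <- res$emitted$kind[1]
          outR[m] <- res$emitted$requirement[1]
        }
        state <- res$state
      } else if (kind == "pellet_removed") {
        res <- .advance(state, spec, tm, kind, ratchet)
        m <- m + 1L
        outT[m] <- tm; outK[m] <- kind; outR[m] <- NA_integer_
        if (!is.null(res$emitted)) {
          m <- m + 1L
          outT[m] <- tm; outK[m] <- "pellet_dispensed"
          outR[m] <- NA_integer_
        }
        state <- res$state
      } else {
        stopf("unknown stream event kind '%s' at row %d", kind, i)
      }
    }
    ts <- c(ts, outT[seq_len(m)]); kd <- c(kd, outK[seq_len(m)])
    rq <- c(rq, outR[seq_len(m)])
  }
  eventLog(data.frame(timestamp = ts, kind = kd, requirement = rq,
                      stringsAsFactors = FALSE),
           spec, sessionId = sessionId, subjectId = subjectId, group = group)
}
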