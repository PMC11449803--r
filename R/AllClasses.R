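#' @include utils.R
NULL

## Event vocabulary of a two-port pellet-dispensing operant device:
## nose-pokes at either port, pellet dispensing, and pellet retrieval
## (all detected by infra-red beams on the physical device).
EVENT_KINDS <- c("poke_left", "poke_right", "pellet_dispensed",
                 "pellet_removed")
POKE_KINDS <- c("poke_left", "poke_right")
SCHEDULE_KINDS <- c("FR", "VR", "PR", "RPR", "EXT", "FREE")
SIDES <- c("left", "right")

# ---------------------------------------------------------------------------
# ScheduleSpec
# ---------------------------------------------------------------------------

#' Operant schedule specification
#'
#' An S4 class describing one operant task: fixed ratio (`FR`), variable
#' ratio (`VR`), exponential progressive ratio (`PR`), re-setting progressive
#' ratio (`RPR`, the PR variant whose requirement drops back to 1 after a
#' sustained lapse in poking), extinction (`EXT`, responding recorded but
#' never rewarded) and magazine training (`FREE`, a pellet is dispensed each
#' time one is removed from the magazine).
#'
#' The progressive-ratio requirement at trial \eqn{n} is
#' \eqn{\mathrm{round}(s\,e^{rn} - s)} with a floor of 1, where \eqn{r} is
#' `prRate` (default 0.2) and \eqn{s} is `prScale` (default 5), giving the
#' requirement sequence 1, 2, 4, 6, 9, 12, ... Variable-ratio requirements
#' are drawn i.i.d. uniformly on `[rangeLow, rangeHigh]` per trial.
#'
#' @slot kind character; one of `"FR"`, `"VR"`, `"PR"`, `"RPR"`, `"EXT"`,
#'   `"FREE"`.
#' @slot ratio integer; pokes per pellet (FR only).
#' @slot rangeLow,rangeHigh integers; VR draw range (VR only).
#' @slot prRate,prScale numerics; progressive-ratio growth rate and scale.
#' @slot targetSide character; `"left"` or `"right"` — the rewarded port,
#'   fixed within a session.
#' @slot inactivityResetS numeric; seconds of poke inactivity after which an
#'   RPR schedule resets its requirement to 1 (default 600 s).
#' @slot sessionDurationS numeric; device access duration in seconds.
#'
#' @seealso [scheduleSpec()], [requiredPokes()], [applyReversal()]
#' @export
setClass("ScheduleSpec",
  representation(kind = "character", ratio = "integer",
                 rangeLow = "integer", rangeHigh = "integer",
                 prRate = "numeric", prScale = "numeric",
                 targetSide = "character", inactivityResetS = "numeric",
                 sessionDurationS = "numeric"),
  prototype(kind = "FR", ratio = 1L, rangeLow = 1L, rangeHigh = 1L,
            prRate = 0.2, prScale = 5, targetSide = "left",
            inactivityResetS = 600, sessionDurationS = 10800))

setValidity("ScheduleSpec", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% SCHEDULE_KINDS)
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(SCHEDULE_KINDS, collapse = ", ")))
  if (length(object@targetSide) != 1L || !object@targetSide %in% SIDES)
    msg <- c(msg, "targetSide must be 'left' or 'right'")
  if (identical(object@kind, "FR") &&
      (is.na(object@ratio) || object@ratio < 1L))
    msg <- c(msg, "FR ratio must be a positive integer")
  if (identical(object@kind, "VR")) {
    if (is.na(object@rangeLow) || is.na(object@rangeHigh) ||
        object@rangeLow < 1L || object@rangeLow > object@rangeHigh)
      msg <- c(msg, "VR requires 1 <= rangeLow <= rangeHigh")
  }
  if (object@kind %in% c("PR", "RPR") && object@prRate <= 0)
    msg <- c(msg, "prRate must be > 0")
  if (!is.na(object@inactivityResetS) && object@inactivityResetS <= 0)
    msg <- c(msg, "inactivityResetS must be positive (may be Inf)")
  if (is.na(object@sessionDurationS) || object@sessionDurationS <= 0)
    msg <- c(msg, "sessionDurationS must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an operant schedule specification
#'
#' @param kind schedule kind: `"FR"`, `"VR"`, `"PR"`, `"RPR"`, `"EXT"` or
#'   `"FREE"`.
#' @param ratio pokes per pellet for FR schedules.
#' @param rangeLow,rangeHigh inclusive draw range for VR schedules
#'   (e.g. 1 and 5 for VR5, 6 and 10 for VR10, 11 and 20 for VR20).
#' @param prRate,prScale progressive-ratio constants (defaults 0.2 and 5).
#' @param targetSide rewarded port, `"left"` (default) or `"right"`.
#' @param inactivityResetS RPR inactivity window in seconds (default 600,
#'   i.e. 10 min); may be `Inf`, in which case RPR behaves exactly as PR.
#' @param sessionDurationS session length in seconds (default 10800 = 3 h).
#' @return A validated [ScheduleSpec-class] object.
#' @examples
#' scheduleSpec("FR", ratio = 5)
#' scheduleSpec("VR", rangeLow = 1, rangeHigh = 5)
#' scheduleSpec("RPR", inactivityResetS = 600)
#' @export
scheduleSpec <- function(kind, ratio = 1, rangeLow = 1, rangeHigh = 1,
                         prRate = 0.2, prScale = 5,
                         targetSide = "left", inactivityResetS = 600,
                         sessionDurationS = 10800) {
  new("ScheduleSpec", kind = as.character(kind), ratio = as.integer(ratio),
      rangeLow = as.integer(rangeLow), rangeHigh = as.integer(rangeHigh),
      prRate = as.numeric(prRate), prScale = as.numeric(prScale),
      targetSide = as.character(targetSide),
      inactivityResetS = as.numeric(inactivityResetS),
      sessionDurationS = as.numeric(sessionDurationS))
}

setMethod("show", "ScheduleSpec", function(object) {
  detail <- switch(object@kind,
    FR = sprintf("FR%d", object@ratio),
    VR = sprintf("VR[%d-%d]", object@rangeLow, object@rangeHigh),
    PR = sprintf("PR(rate=%g, scale=%g)", object@prRate, object@prScale),
    RPR = sprintf("RPR(rate=%g, scale=%g, reset=%gs)", object@prRate,
                  object@prScale, object@inactivityResetS),
    object@kind)
  cat(sprintf("ScheduleSpec: %s, target=%s, duration=%gs\n",
              detail, object@targetSide, object@sessionDurationS))
})

# ---------------------------------------------------------------------------
# EventLog
# ---------------------------------------------------------------------------

#' Operant session event log
#'
#' Ordered, timestamped device events for one operant session, with session
#' metadata and the schedule in force. Timestamps are seconds from device
#' access (time 0). Events are stored as a data.frame with columns
#' `timestamp` (numeric seconds), `kind` (one of `poke_left`, `poke_right`,
#' `pellet_dispensed`, `pellet_removed`) and `requirement` (the ratio
#' requirement in force when the event occurred; `NA` for `pellet_removed`
#' and for schedules with no requirement, i.e. extinction and magazine
#' training).
#'
#' Validity enforces: non-negative sorted timestamps (ties broken by row
#' order) not exceeding the access duration, event kinds from the closed
#' vocabulary, and that a `pellet_removed` never precedes its matching
#' `pellet_dispensed`.
#'
#' @slot sessionId,subjectId,group character metadata labels.
#' @slot schedule the [ScheduleSpec-class] in force.
#' @slot accessDuration numeric; seconds of device access.
#' @slot events data.frame of events (see Description).
#'
#' @seealso [eventLog()], [readEventLog()], [scoreSession()]
#' @export
setClass("EventLog",
  representation(sessionId = "character", subjectId = "character",
                 group = "character", schedule = "ScheduleSpec",
                 accessDuration = "numeric", events = "data.frame"))

setValidity("EventLog", function(object) {
  ev <- object@events
  msg <- character()
  need <- c("timestamp", "kind", "requirement")
  if (!all(need %in% names(ev)))
    return(sprintf("events must have columns %s", paste(need, collapse = ", ")))
  if (nrow(ev)) {
    if (any(!ev$kind %in% EVENT_KINDS))
      msg <- c(msg, sprintf("unknown event kind(s): %s",
                            paste(unique(setdiff(ev$kind, EVENT_KINDS)),
                                  collapse = ", ")))
    if (any(is.na(ev$timestamp)) || any(ev$timestamp < 0))
      msg <- c(msg, "timestamps must be non-negative")
    else if (is.unsorted(ev$timestamp))
      msg <- c(msg, sprintf("timestamps not sorted; first offending row %d",
                            which(diff(ev$timestamp) < 0)[1] + 1L))
    if (any(ev$timestamp > object@accessDuration, na.rm = TRUE))
      msg <- c(msg, "timestamps exceed accessDuration")
    disp <- cumsum(ev$kind == "pellet_dispensed")
    remv <- cumsum(ev$kind == "pellet_removed")
    if (any(remv > disp))
      msg <- c(msg, "pellet_removed precedes matching pellet_dispensed")
    if (any(!is.na(ev$requirement) & ev$kind == "pellet_removed"))
      msg <- c(msg, "pellet_removed events must not carry a requirement")
    needsReq <- ev$kind %in% c(POKE_KINDS, "pellet_dispensed")
    if (!object@schedule@kind %in% c("EXT", "FREE") &&
        any(needsReq & is.na(ev$requirement)))
      msg <- c(msg, "pokes and dispenses must carry the requirement in force")
    if (any(ev$requirement < 1L, na.rm = TRUE))
      msg <- c(msg, "requirements must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an event log
#'
#' @param events data.frame with columns `timestamp`, `kind`, `requirement`
#'   (see [EventLog-class]); zero rows allowed.
#' @param schedule a [ScheduleSpec-class].
#' @param sessionId,subjectId,group character metadata labels.
#' @param accessDuration seconds of device access; defaults to the
#'   schedule's session duration.
#' @return A validated [EventLog-class].
#' @export
eventLog <- function(events, schedule, sessionId = "s1", subjectId = "r1",
                     group = "none",
                     accessDuration = schedule@sessionDurationS) {
  events <- data.frame(timestamp = as.numeric(events$timestamp),
                       kind = as.character(events$kind),
                       requirement = as.integer(events$requirement),
                       stringsAsFactors = FALSE)
  new("EventLog", sessionId = sessionId, subjectId = subjectId,
      group = group, schedule = schedule,
      accessDuration = as.numeric(accessDuration), events = events)
}

emptyEvents <- function() {
  data.frame(timestamp = numeric(0), kind = character(0),
             requirement = integer(0), stringsAsFactors = FALSE)
}

setMethod("show", "EventLog", function(object) {
  ev <- object@events
  cat(sprintf("EventLog: session %s, subject %s (group %s)\n",
              object@sessionId, object@subjectId, object@group))
  cat(sprintf("  schedule %s/%s, access %gs, %d events (%d pokes, %d pellets)\n",
              object@schedule@kind, object@schedule@targetSide,
              object@accessDuration, nrow(ev),
              sum(ev$kind %in% POKE_KINDS),
              sum(ev$kind == "pellet_dispensed")))
})

#' @describeIn eventLog number of events in the log.
#' @param x an `EventLog`.
#' @export
setMethod("length", "EventLog", function(x) nrow(x@events))

#' Accessors for EventLog components
#'
#' `events()` returns the event table, `schedule()` the schedule in force,
#' `subjectId()` and `groupLabel()` the metadata labels.
#'
#' @param object an [EventLog-class].
#' @return `events()`: data.frame; `schedule()`: [ScheduleSpec-class];
#'   others: character scalars.
#' @name eventlog-accessors
NULL

#' @rdname eventlog-accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))
#' @rdname eventlog-accessors
#' @export
setMethod("events", "EventLog", function(object) object@events)

#' @rdname eventlog-accessors
#' @export
setGeneric("schedule", function(object) standardGeneric("schedule"))
#' @rdname eventlog-accessors
#' @export
setMethod("schedule", "EventLog", function(object) object@schedule)

#' @rdname eventlog-accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname eventlog-accessors
#' @export
setMethod("subjectId", "EventLog", function(object) object@subjectId)

#' @rdname eventlog-accessors
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))
#' @rdname eventlog-accessors
#' @export
setMethod("groupLabel", "EventLog", function(object) object@group)

# ---------------------------------------------------------------------------
# DeviceState
# ---------------------------------------------------------------------------

#' Mutable ratio/trial state of the operant device
#'
#' Book-keeping carried by the device between events: the current trial
#' number, pokes accumulated toward the current requirement, the requirement
#' in force, pellets dispensed so far, whether a pellet is sitting in the
#' magazine well, the time of the last poke, and (for re-setting PR) how many
#' times the schedule has reset.
#'
#' @seealso [newDeviceState()], [advanceDevice()]
#' @export
setClass("DeviceState",
  representation(trialN = "integer", pokesTowardRatio = "integer",
                 currentRequirement = "integer", pelletsDispensed = "integer",
                 pelletInWell = "logical", lastActivityS = "numeric",
                 resets = "integer"))

setValidity("DeviceState", function(object) {
  msg <- character()
  if (object@trialN < 1L) msg <- c(msg, "trialN must be >= 1")
  if (object@pokesTowardRatio < 0L)
    msg <- c(msg, "pokesTowardRatio must be >= 0")
  if (!is.na(object@currentRequirement) &&
      object@pokesTowardRatio >= object@currentRequirement)
    msg <- c(msg, "pokesTowardRatio must be < currentRequirement at rest")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DeviceState", function(object) {
  cat(sprintf(paste0("DeviceState: trial %d, %d/%s pokes, %d pellets, ",
                     "%d resets\n"),
              object@trialN, object@pokesTowardRatio,
              ifelse(is.na(object@currentRequirement), "-",
                     object@currentRequirement),
              object@pelletsDispensed, object@resets))
})

# ---------------------------------------------------------------------------
# AgentParams
# ---------------------------------------------------------------------------

#' Stochastic behaving-agent parameters
#'
#' Parameters of the synthetic two-choice reinforcement-learning agent used
#' to generate operant event logs: a delta-rule value learner with separate
#' learning rates for rewarded (`alphaPos`) and unrewarded (`alphaNeg`)
#' pokes, softmax choice with inverse temperature `beta` and a perseveration
#' bonus `kappa` toward the previous choice, log-normal inter-poke intervals,
#' a per-poke hazard of disengaging into a log-normal-duration pause, and an
#' exponential pellet-retrieval delay.
#'
#' All parameters are synthetic: they describe the generative model of the
#' simulator, not any fitted animal.
#'
#' @slot alphaPos,alphaNeg learning rates in \[0, 1\] applied on rewarded and
#'   unrewarded pokes respectively.
#' @slot beta softmax inverse temperature (>= 0).
#' @slot kappa perseveration bonus added to the logit of repeating the
#'   previous side (real; positive = sticky).
#' @slot qInit numeric length-2 initial action values (left, right).
#' @slot ipiMu,ipiSigma log-scale mean and sd of inter-poke intervals (s).
#' @slot pauseHazard per-poke probability of entering a pause in \[0, 1\].
#' @slot pauseMu,pauseSigma log-scale mean and sd of pause durations (s).
#' @slot retrievalMu mean pellet-retrieval delay (s, exponential).
#'
#' @seealso [agentParams()], [simulateSession()], [fitAgentParams()]
#' @export
setClass("AgentParams",
  representation(alphaPos = "numeric", alphaNeg = "numeric",
                 beta = "numeric", kappa = "numeric", qInit = "numeric",
                 ipiMu = "numeric", ipiSigma = "numeric",
                 pauseHazard = "numeric", pauseMu = "numeric",
                 pauseSigma = "numeric", retrievalMu = "numeric"))

setValidity("AgentParams", function(object) {
  msg <- character()
  inUnit <- function(x) length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
  if (!inUnit(object@alphaPos)) msg <- c(msg, "alphaPos must be in [0,1]")
  if (!inUnit(object@alphaNeg)) msg <- c(msg, "alphaNeg must be in [0,1]")
  if (object@beta < 0) msg <- c(msg, "beta must be >= 0")
  if (length(object@qInit) != 2L || any(!is.finite(object@qInit)))
    msg <- c(msg, "qInit must be two finite values")
  if (!inUnit(object@pauseHazard)) msg <- c(msg, "pauseHazard must be in [0,1]")
  for (s in c("ipiSigma", "pauseSigma", "retrievalMu"))
    if (slot(object, s) <= 0) msg <- c(msg, sprintf("%s must be > 0", s))
  if (length(msg)) msg else TRUE
})

#' Construct agent parameters
#'
#' Defaults give a moderately engaged learner poking every few seconds with
#' occasional minute-scale pauses; see [AgentParams-class] for the meaning of
#' each parameter.
#'
#' @param alphaPos,alphaNeg,beta,kappa,qInit,ipiMu,ipiSigma,pauseHazard
#'   see [AgentParams-class].
#' @param pauseMu,pauseSigma,retrievalMu see [AgentParams-class].
#' @return A validated [AgentParams-class].
#' @examples
#' agentParams(alphaPos = 0.4, alphaNeg = 0.2, beta = 3)
#' @export
agentParams <- function(alphaPos = 0.35, alphaNeg = 0.2, beta = 3,
                        kappa = 0.3, qInit = c(0, 0),
                        ipiMu = log(4), ipiSigma = 0.6,
                        pauseHazard = 0.02, pauseMu = log(60),
                        pauseSigma = 0.8, retrievalMu = 5) {
  new("AgentParams", alphaPos = alphaPos, alphaNeg = alphaNeg, beta = beta,
      kappa = kappa, qInit = as.numeric(qInit), ipiMu = ipiMu,
      ipiSigma = ipiSigma, pauseHazard = pauseHazard, pauseMu = pauseMu,
      pauseSigma = pauseSigma, retrievalMu = retrievalMu)
}

setMethod("show", "AgentParams", function(object) {
  cat(sprintf(paste0("AgentParams: alpha+=%.3g alpha-=%.3g beta=%.3g ",
                     "kappa=%.3g\n  IPI lognormal(%.3g, %.3g) s, pause ",
                     "hazard %.3g, retrieval %.3g s\n"),
              object@alphaPos, object@alphaNeg, object@beta, object@kappa,
              object@ipiMu, object@ipiSigma, object@pauseHazard,
              object@retrievalMu))
})

# ---------------------------------------------------------------------------
# CohortDesign
# ---------------------------------------------------------------------------

#' Cohort simulation design
#'
#' Describes a simulated operant cohort: one or more groups (label, agent
#' parameters, number of subjects) run through an ordered protocol of
#' schedule stages. A stage may request an un-cued reversal, in which case
#' the target side is flipped relative to the preceding stage before the
#' stage's sessions are run; action values are carried across sessions
#' within a subject, so reversal stages expose perseveration.
#'
#' @slot groups list of `list(label=, params=, n=)` entries.
#' @slot protocol list of `list(spec=, nSessions=, reverse=)` stages.
#' @slot masterSeed integer; per-subject seeds are derived deterministically
#'   from it.
#'
#' @seealso [cohortDesign()], [simulateCohort()]
#' @export
setClass("CohortDesign",
  representation(groups = "list", protocol = "list", masterSeed = "integer"))

setValidity("CohortDesign", function(object) {
  msg <- character()
  if (!length(object@groups)) msg <- c(msg, "at least one group required")
  for (g in object@groups) {
    if (!all(c("label", "params", "n") %in% names(g)) ||
        !is(g$params, "AgentParams") || g$n < 1)
      msg <- c(msg, "each group needs label, AgentParams params, n >= 1")
  }
  if (!length(object@protocol)) msg <- c(msg, "protocol must be non-empty")
  for (st in object@protocol) {
    if (!is(st$spec, "ScheduleSpec") || (st$nSessions %||% 0) < 1)
      msg <- c(msg, "each stage needs a ScheduleSpec and nSessions >= 1")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' Construct a cohort design
#'
#' @param groups list of groups, each `list(label = "control",
#'   params = agentParams(), n = 10)`.
#' @param protocol list of stages, each `list(spec = scheduleSpec(...),
#'   nSessions = 2, reverse = FALSE)`; `reverse = TRUE` flips the target
#'   side relative to the stage before (un-cued between-session reversal).
#' @param masterSeed integer master seed.
#' @return A validated [CohortDesign-class].
#' @export
cohortDesign <- function(groups, protocol, masterSeed = 1L) {
  protocol <- lapply(protocol, function(st) {
    st$reverse <- isTRUE(st$reverse); st
  })
  new("CohortDesign", groups = groups, protocol = protocol,
      masterSeed = as.integer(masterSeed))
}

setMethod("show", "CohortDesign", function(object) {
  cat(sprintf("CohortDesign: %d group(s), %d stage(s), master seed %d\n",
              length(object@groups), length(object@protocol),
              object@masterSeed))
  for (g in object@groups)
    cat(sprintf("  %s: n=%d\n", g$label, g$n))
})

# ---------------------------------------------------------------------------
# ABA classes
# ---------------------------------------------------------------------------

#' Activity-based anorexia protocol configuration
#'
#' Fixed design constants of the ABA paradigm: a 7-day baseline with ad
#' libitum food, then time-restricted feeding (90 min/day at dark-phase
#' onset, 1100-1230 h) with unlimited wheel access for at most 10 days or
#' until body weight falls below 80% of baseline (the susceptibility
#' criterion). Running in the hour before the feeding window (1000-1100 h)
#' counts as food anticipatory activity (FAA). Days with weight above 85% of
#' baseline are tallied as a weight-maintenance measure.
#'
#' @slot baselineDays integer, default 7.
#' @slot maxAbaDays integer, default 10.
#' @slot feedingStartH,feedingEndH clock hours of the feeding window
#'   (defaults 11 and 12.5).
#' @slot faaStartH,faaEndH clock hours of the FAA window (defaults 10, 11).
#' @slot susceptibilityFraction removal threshold as a fraction of baseline
#'   weight (default 0.80).
#' @slot maintenanceFraction weight-maintenance threshold (default 0.85).
#'
#' @seealso [abaConfig()], [classifyOutcome()]
#' @export
setClass("AbaConfig",
  representation(baselineDays = "integer", maxAbaDays = "integer",
                 feedingStartH = "numeric", feedingEndH = "numeric",
                 faaStartH = "numeric", faaEndH = "numeric",
                 susceptibilityFraction = "numeric",
                 maintenanceFraction = "numeric"),
  prototype(baselineDays = 7L, maxAbaDays = 10L, feedingStartH = 11,
            feedingEndH = 12.5, faaStartH = 10, faaEndH = 11,
            susceptibilityFraction = 0.80, maintenanceFraction = 0.85))

setValidity("AbaConfig", function(object) {
  msg <- character()
  if (object@baselineDays < 1L || object@maxAbaDays < 1L)
    msg <- c(msg, "baselineDays and maxAbaDays must be >= 1")
  if (!(object@susceptibilityFraction > 0 &&
        object@susceptibilityFraction < object@maintenanceFraction &&
        object@maintenanceFraction < 1))
    msg <- c(msg, "need 0 < susceptibilityFraction < maintenanceFraction < 1")
  if (object@faaEndH > object@feedingStartH)
    msg <- c(msg, "FAA window must end at or before the feeding window")
  if (object@faaStartH >= object@faaEndH ||
      object@feedingStartH >= object@feedingEndH)
    msg <- c(msg, "windows must have positive length")
  if (length(msg)) msg else TRUE
})

#' Construct an ABA protocol configuration
#'
#' @param baselineDays,maxAbaDays,susceptibilityFraction,maintenanceFraction
#'   see [AbaConfig-class].
#' @param feedingStartH,feedingEndH,faaStartH,faaEndH clock hours of the
#'   feeding and food-anticipation windows.
#' @return A validated [AbaConfig-class].
#' @export
abaConfig <- function(baselineDays = 7, maxAbaDays = 10,
                      feedingStartH = 11, feedingEndH = 12.5,
                      faaStartH = 10, faaEndH = 11,
                      susceptibilityFraction = 0.80,
                      maintenanceFraction = 0.85) {
  new("AbaConfig", baselineDays = as.integer(baselineDays),
      maxAbaDays = as.integer(maxAbaDays),
      feedingStartH = feedingStartH, feedingEndH = feedingEndH,
      faaStartH = faaStartH, faaEndH = faaEndH,
      susceptibilityFraction = susceptibilityFraction,
      maintenanceFraction = maintenanceFraction)
}

#' Synthetic ABA rat generator parameters
#'
#' Parameters of the toy energy-balance model used to generate daily ABA
#' records. Under restriction, weight evolves as
#' \deqn{BW_{d+1} = BW_d + g\,\mathrm{intake}_d - c\,\mathrm{revs}_d/1000 -
#'   \ell + \epsilon}
#' where \eqn{g} is `intakeGain`, \eqn{c} is `runCost` and \eqn{\ell} is
#' `basalLoss`. The generator is an invented synthetic stand-in for rat
#' physiology; only the downstream classification and phenotype metrics
#' claim fidelity to the paradigm's definitions.
#'
#' @slot bw0 baseline body weight (g).
#' @slot intakeGain grams of body weight gained per gram of food.
#' @slot runCost grams of body weight lost per 1000 wheel revolutions.
#' @slot basalLoss grams/day basal loss under restriction.
#' @slot appetite mean 90-min intake on ABA day 1 (g).
#' @slot appetiteSlope grams/day adaptation of intake across ABA days.
#' @slot runDrive mean daily wheel revolutions at baseline.
#' @slot runMult multiplier on `runDrive` under food restriction
#'   (starvation-induced hyperactivity when > 1).
#' @slot faaShare length-2 fraction of daily running falling in the FAA hour
#'   at (baseline, ABA).
#' @slot noiseWeight,noiseIntake,noiseRun Gaussian noise SDs for the daily
#'   weight step (g), intake (g) and running (revolutions).
#'
#' @seealso [ratSimParams()], [simulateAbaRat()]
#' @export
setClass("RatSimParams",
  representation(bw0 = "numeric", intakeGain = "numeric",
                 runCost = "numeric", basalLoss = "numeric",
                 appetite = "numeric", appetiteSlope = "numeric",
                 runDrive = "numeric", runMult = "numeric",
                 faaShare = "numeric", noiseWeight = "numeric",
                 noiseIntake = "numeric", noiseRun = "numeric"))

setValidity("RatSimParams", function(object) {
  msg <- character()
  for (s in c("bw0", "intakeGain", "basalLoss", "runDrive", "runMult",
              "noiseWeight", "noiseIntake", "noiseRun"))
    if (length(slot(object, s)) != 1L || slot(object, s) < 0)
      msg <- c(msg, sprintf("%s must be a single non-negative number", s))
  if (object@bw0 <= 0) msg <- c(msg, "bw0 must be positive")
  if (object@runCost < 0) msg <- c(msg, "runCost must be >= 0")
  if (object@appetite < 0) msg <- c(msg, "appetite must be >= 0")
  if (length(object@faaShare) != 2L || any(object@faaShare < 0) ||
      any(object@faaShare > 1))
    msg <- c(msg, "faaShare must be two fractions in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Construct synthetic ABA rat parameters
#'
#' Defaults describe a young female rat of ~250 g baseline weight running
#' ~6000 revolutions/day at baseline, roughly doubling under restriction,
#' eating ~8 g in the 90-min window on day 1 with a +0.8 g/day adaptation
#' slope. These are synthetic, field-realistic values, not fits.
#'
#' @param bw0,intakeGain,runCost,basalLoss,appetite,appetiteSlope see
#'   [RatSimParams-class].
#' @param runDrive,runMult,faaShare,noiseWeight,noiseIntake,noiseRun see
#'   [RatSimParams-class].
#' @return A validated [RatSimParams-class].
#' @export
ratSimParams <- function(bw0 = 250, intakeGain = 0.55, runCost = 0.55,
                         basalLoss = 7, appetite = 8, appetiteSlope = 0.8,
                         runDrive = 6000, runMult = 1.9,
                         faaShare = c(0.06, 0.22), noiseWeight = 1.5,
                         noiseIntake = 1.2, noiseRun = 900) {
  new("RatSimParams", bw0 = bw0, intakeGain = intakeGain, runCost = runCost,
      basalLoss = basalLoss, appetite = appetite,
      appetiteSlope = appetiteSlope, runDrive = runDrive, runMult = runMult,
      faaShare = as.numeric(faaShare), noiseWeight = noiseWeight,
      noiseIntake = noiseIntake, noiseRun = noiseRun)
}

#' ABA phenotype outcome
#'
#' Derived per-rat outcome of ABA exposure: the susceptibility label (weight
#' fell below the removal threshold within the protocol), the removal day if
#' so, days spent above the 85% maintenance threshold, mean daily percent
#' weight loss, the lowest percent body weight reached, the change in the
#' food-anticipatory fraction of daily running relative to baseline (with
#' the absolute FAA revolutions also exposed), mean intake over the first 7
#' ABA days, and phase means of daily wheel revolutions.
#'
#' @slot subjectId character.
#' @slot susceptible logical; `TRUE` iff `removalDay` is present.
#' @slot removalDay integer ABA day of removal, or `NA`.
#' @slot daysAbove85 integer count of ABA days above the maintenance
#'   threshold.
#' @slot meanDailyPctLoss mean day-over-day percent body-weight decrement.
#' @slot lowestPctBw lowest percent of baseline body weight reached.
#' @slot faaChange mean ABA FAA fraction minus mean baseline FAA fraction.
#' @slot faaBaseline,faaAba phase means of the FAA fraction of daily running.
#' @slot faaAbsBaseline,faaAbsAba phase means of absolute FAA revolutions.
#' @slot meanIntake7d mean 90-min intake over the first 7 ABA days (or until
#'   removal).
#' @slot baselineRevs,abaRevs phase means of daily revolutions.
#'
#' @seealso [classifyOutcome()], [phenotypeMetrics()]
#' @export
setClass("AbaOutcome",
  representation(subjectId = "character", susceptible = "logical",
                 removalDay = "integer", daysAbove85 = "integer",
                 meanDailyPctLoss = "numeric", lowestPctBw = "numeric",
                 faaChange = "numeric", faaBaseline = "numeric",
                 faaAba = "numeric", faaAbsBaseline = "numeric",
                 faaAbsAba = "numeric", meanIntake7d = "numeric",
                 baselineRevs = "numeric", abaRevs = "numeric"))

setValidity("AbaOutcome", function(object) {
  if (object@susceptible != !is.na(object@removalDay))
    return("susceptible must hold exactly when removalDay is present")
  TRUE
})

setMethod("show", "AbaOutcome", function(object) {
  cat(sprintf("AbaOutcome for %s: %s%s\n", object@subjectId,
              if (object@susceptible) "susceptible" else "resistant",
              if (object@susceptible)
                sprintf(" (removed day %d)", object@removalDay) else ""))
  cat(sprintf("  days above 85%%: %d; lowest %%BW %.1f; mean daily loss %.2f%%\n",
              object@daysAbove85, object@lowestPctBw,
              object@meanDailyPctLoss))
  cat(sprintf("  FAA change %+.3f; mean 7-day intake %.1f g\n",
              object@faaChange, object@meanIntake7d))
})

# ---------------------------------------------------------------------------
# SpatialProfile
# ---------------------------------------------------------------------------

#' Cortical-depth spatial profile of transcript co-expression classes
#'
#' Per-bin proportions of double-labelled, exclusively-Htr1a and
#' exclusively-Htr2a cells among all Htr1a/Htr2a-positive cells, binned by
#' distance from the Layer I midline, with the trapezoidal area under each
#' class's proportion curve.
#'
#' @slot nBins integer number of distance bins (default 50).
#' @slot binEdges numeric length `nBins + 1` micrometre grid.
#' @slot binCentres numeric bin midpoints (µm).
#' @slot counts integer matrix `nBins x 3` of positive-cell counts per bin
#'   and class (columns `double`, `excl_htr1a`, `excl_htr2a`).
#' @slot proportions numeric matrix `nBins x 3`; rows of occupied bins sum
#'   to 1, unoccupied bins are `NA`.
#' @slot auc named numeric length 3; trapezoidal area (fraction x µm) under
#'   each class curve, with empty interior bins linearly bridged and
#'   leading/trailing empty bins dropped.
#'
#' @seealso [spatialProfile()]
#' @export
setClass("SpatialProfile",
  representation(nBins = "integer", binEdges = "numeric",
                 binCentres = "numeric", counts = "matrix",
                 proportions = "matrix", auc = "numeric"))

setValidity("SpatialProfile", function(object) {
  msg <- character()
  if (length(object@binEdges) != object@nBins + 1L)
    msg <- c(msg, "binEdges must have nBins + 1 entries")
  occ <- rowSums(object@counts) > 0
  ps <- rowSums(object@proportions)
  if (any(occ) && any(abs(ps[occ] - 1) > 1e-9))
    msg <- c(msg, "occupied-bin class proportions must sum to 1")
  if (any(object@auc < 0, na.rm = TRUE)) msg <- c(msg, "auc must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpatialProfile", function(object) {
  cat(sprintf("SpatialProfile: %d bins over [0, %g] um, %d positive cells\n",
              object@nBins, max(object@binEdges), sum(object@counts)))
  cat("  AUC (fraction*um):",
      paste(sprintf("%s=%.1f", names(object@auc), object@auc),
            collapse = ", "), "\n")
})
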