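#' @include AllClasses.R
NULL

#' Moving-window learning-criterion result
#'
#' Result of scanning a session's pokes for the learning criterion
#' (by default, at least 80 target pokes within a 100-poke moving window).
#'
#' @slot reached logical.
#' @slot pokeIndex integer 1-based index of the poke achieving criterion
#'   (`NA` if unreached).
#' @slot timeToCriterionS seconds from the first poke to the achieving poke.
#' @slot totalPokes,targetPokes,nontargetPokes counts up to and including
#'   the achieving poke (`NA` if unreached); target + nontarget = total.
#'
#' @seealso [detectCriterion()]
#' @export
setClass("CriterionResult",
  representation(reached = "logical", pokeIndex = "integer",
                 timeToCriterionS = "numeric", totalPokes = "integer",
                 targetPokes = "integer", nontargetPokes = "integer"))

setValidity("CriterionResult", function(object) {
  if (object@reached &&
      (is.na(object@pokeIndex) || is.na(object@timeToCriterionS)))
    return("reached criterion must carry pokeIndex and time")
  if (object@reached &&
      object@targetPokes + object@nontargetPokes != object@totalPokes)
    return("target + nontarget pokes must equal total pokes")
  TRUE
})

setMethod("show", "CriterionResult", function(object) {
  if (object@reached)
    cat(sprintf(paste0("Criterion reached at poke %d (%.1f s from first ",
                       "poke; %d target / %d non-target)\n"),
                object@pokeIndex, object@timeToCriterionS,
                object@targetPokes, object@nontargetPokes))
  else cat("Criterion not reached\n")
})

.pokeTable <- function(log) {
  ev <- log@events
  keep <- ev$kind %in% POKE_KINDS
  p <- ev[keep, , drop = FALSE]
  p$target <- (p$kind == "poke_left") ==
    (log@schedule@targetSide == "left")
  p
}

#' Binned response accuracy
#'
#' Accuracy (target pokes / all pokes) overall and per time bin. A 3-h
#' session with the default 30-min bin yields exactly 6 bins; bins with no
#' pokes carry `NA`, and a partial final bin is reported with its own
#' fraction, never merged.
#'
#' @param log an [EventLog-class].
#' @param binS bin width in seconds (default 1800 = 30 min).
#' @return List with `overall` (fraction, `NA` if the session has no
#'   pokes), `bins` (vector of per-bin fractions), and `binCounts`
#'   (pokes per bin; sums to the total poke count).
#' @examples
#' log <- simulateSession(agentParams(), scheduleSpec("FR", ratio = 1),
#'                        seed = 1)
#' binnedAccuracy(log)$overall
#' @export
binnedAccuracy <- function(log, binS = 1800) {
  stopifnot(is(log, "EventLog"), binS > 0)
  p <- .pokeTable(log)
  nBins <- max(1L, as.integer(ceiling(log@accessDuration / binS)))
  if (!nrow(p))
    return(list(overall = NA_real_, bins = rep(NA_real_, nBins),
                binCounts = rep(0L, nBins)))
  idx <- pmin(nBins, as.integer(floor(p$timestamp / binS)) + 1L)
  counts <- tabulate(idx, nBins)
  hits <- vapply(seq_len(nBins),
                 function(b) sum(p$target[idx == b]), numeric(1))
  bins <- ifelse(counts > 0, hits / counts, NA_real_)
  list(overall = sum(p$target) / nrow(p), bins = bins, binCounts = counts)
}

#' Detect the moving-window learning criterion
#'
#' Scans pokes in order; the criterion is reached at the first poke `k`
#' such that among the last `min(k, window)` pokes the number of target
#' pokes is at least `threshold`. Before `window` pokes exist the window is
#' all pokes so far, so e.g. 80 consecutive target pokes reach the default
#' criterion at poke 80. Time to criterion is measured from the first poke.
#'
#' @param log an [EventLog-class].
#' @param window moving-window length in pokes (default 100).
#' @param threshold required target pokes within the window (default 80).
#' @return A [CriterionResult-class]; `reached = FALSE` (with `NA` fields)
#'   when the criterion is never met.
#' @export
detectCriterion <- function(log, window = 100L, threshold = 80L) {
  stopifnot(is(log, "EventLog"))
  window <- as.integer(window); threshold <- as.integer(threshold)
  if (window < threshold || threshold < 1L)
    stopf("need window >= threshold >= 1")
  p <- .pokeTable(log)
  n <- nrow(p)
  notReached <- new("CriterionResult", reached = FALSE,
                    pokeIndex = NA_integer_, timeToCriterionS = NA_real_,
                    totalPokes = NA_integer_, targetPokes = NA_integer_,
                    nontargetPokes = NA_integer_)
  if (!n) return(notReached)
  cs <- c(0L, cumsum(as.integer(p$target)))
  k <- seq_len(n)
  w <- pmin(k, window)
  inWindow <- cs[k + 1L] - cs[k - w + 1L]
  hit <- which(inWindow >= threshold)
  if (!length(hit)) return(notReached)
  k0 <- hit[1]
  new("CriterionResult", reached = TRUE, pokeIndex = as.integer(k0),
      timeToCriterionS = p$timestamp[k0] - p$timestamp[1],
      totalPokes = as.integer(k0), targetPokes = cs[k0 + 1L],
      nontargetPokes = as.integer(k0) - cs[k0 + 1L])
}

#' Session latency profile
#'
#' Latencies defined by the session's events: time from device access to
#' the first poke (`firstPokeLatencyS`) and to the first target poke
#' (`targetPokeLatencyS`); time from the first poke to earning the first
#' pellet (`firstPelletLatencyS`); and the active session duration, time
#' from first to final poke (`sessionDurationS`). Each is `NA` exactly when
#' its defining event never occurred.
#'
#' @param log an [EventLog-class].
#' @return Named list of the four latencies in seconds.
#' @export
latencyProfile <- function(log) {
  stopifnot(is(log, "EventLog"))
  p <- .pokeTable(log)
  pel <- log@events$timestamp[log@events$kind == "pellet_dispensed"]
  firstPoke <- if (nrow(p)) p$timestamp[1] else NA_real_
  list(
    firstPokeLatencyS = firstPoke,
    targetPokeLatencyS = if (any(p$target)) p$timestamp[p$target][1]
                         else NA_real_,
    firstPelletLatencyS = if (length(pel) && nrow(p)) pel[1] - firstPoke
                          else NA_real_,
    sessionDurationS = if (nrow(p)) p$timestamp[nrow(p)] - firstPoke
                       else NA_real_)
}

#' Reward rate and efficiency
#'
#' Pellets earned, pellets per hour of device access, and non-target pokes
#' per pellet (the reward-efficiency measure; `NA`, with `noPellets =
#' TRUE`, when no pellet was earned).
#'
#' @param log an [EventLog-class].
#' @return Named list `pellets`, `pelletsPerHour`, `nontargetPerPellet`,
#'   `noPellets`.
#' @export
rewardEfficiency <- function(log) {
  stopifnot(is(log, "EventLog"))
  p <- .pokeTable(log)
  pellets <- sum(log@events$kind == "pellet_dispensed")
  nontarget <- sum(!p$target)
  list(pellets = pellets,
       pelletsPerHour = pellets / (log@accessDuration / 3600),
       nontargetPerPellet = if (pellets > 0) nontarget / pellets
                            else NA_real_,
       noPellets = pellets == 0)
}

#' Breakpoint and re-setting engagement metrics
#'
#' For progressive-ratio and re-setting progressive-ratio sessions:
#' the breakpoint is the ratio requirement of the last pellet earned before
#' the first inter-poke gap of at least `inactivityS` seconds, emulating
#' classic session termination within the full access window; the session
#' end counts as a terminal gap, so a session with no such lapse yields the
#' requirement of its final pellet. `firstBreakpoint` is the same quantity
#' computed before the first lapse regardless of later activity (for PR the
#' two coincide; for R-PR it indexes performance before the first reset).
#' Requirement resets (R-PR) are recovered from the logged requirement
#' markers — a poke whose requirement drops below its predecessor's — and
#' target/non-target pokes from the first reset onward are tallied as
#' post-reset engagement.
#'
#' @param log an [EventLog-class] from a PR or RPR session.
#' @param inactivityS inactivity gap in seconds (default 600 = 10 min).
#' @return Named list `breakpoint`, `firstBreakpoint`, `resets`,
#'   `postResetTarget`, `postResetNontarget`, `noPellets`. Breakpoints are
#'   0 (flagged by `noPellets`) when no pellet was earned before the lapse.
#' @export
breakpointMetrics <- function(log, inactivityS = 600) {
  stopifnot(is(log, "EventLog"))
  if (!log@schedule@kind %in% c("PR", "RPR"))
    stopf("breakpoint metrics require a PR or RPR session (got %s)",
          log@schedule@kind)
  ev <- log@events
  p <- .pokeTable(log)
  pel <- ev[ev$kind == "pellet_dispensed", , drop = FALSE]

  lastPelletReqBefore <- function(tmax) {
    keep <- pel$timestamp <= tmax
    if (!any(keep)) 0L else as.integer(tail(pel$requirement[keep], 1))
  }
  if (nrow(p) >= 1L) {
    gaps <- diff(p$timestamp)
    firstGap <- which(gaps >= inactivityS)
    # session end is a terminal gap of infinite length
    cutT <- if (length(firstGap)) p$timestamp[firstGap[1]]
            else p$timestamp[nrow(p)]
    breakpoint <- lastPelletReqBefore(cutT)
  } else {
    breakpoint <- 0L
  }
  firstBreakpoint <- breakpoint

  # requirement-reset markers: logged requirement drops between pokes
  req <- p$requirement
  resetIdx <- if (nrow(p) > 1L) which(diff(req) < 0) + 1L else integer(0)
  resets <- length(resetIdx)
  if (resets) {
    post <- seq(resetIdx[1], nrow(p))
    postT <- sum(p$target[post]); postN <- sum(!p$target[post])
  } else {
    postT <- 0L; postN <- 0L
  }
  list(breakpoint = breakpoint, firstBreakpoint = firstBreakpoint,
       resets = resets, postResetTarget = as.integer(postT),
       postResetNontarget = as.integer(postN),
       noPellets = nrow(pel) == 0L)
}

#' Score a session into all session-level measures
#'
#' One-stop scoring of an event log: overall and binned accuracy, the
#' moving-window criterion, latencies, reward efficiency and (for PR/R-PR)
#' breakpoint metrics, returned as a one-row data.frame suitable for
#' row-binding across sessions.
#'
#' @param log an [EventLog-class].
#' @param binS accuracy bin width in seconds (default 1800).
#' @param window,threshold criterion parameters (defaults 100 and 80).
#' @param inactivityS breakpoint inactivity gap (default 600).
#' @return One-row data.frame; per-bin accuracies are in columns
#'   `acc_bin1`, `acc_bin2`, ... Breakpoint columns are `NA` for non-PR
#'   schedules.
#' @seealso [scoreCohort()]
#' @export
scoreSession <- function(log, binS = 1800, window = 100L, threshold = 80L,
                         inactivityS = 600) {
  acc <- binnedAccuracy(log, binS)
  crit <- detectCriterion(log, window, threshold)
  lat <- latencyProfile(log)
  eff <- rewardEfficiency(log)
  p <- .pokeTable(log)
  bp <- if (log@schedule@kind %in% c("PR", "RPR"))
          breakpointMetrics(log, inactivityS)
        else list(breakpoint = NA_integer_, firstBreakpoint = NA_integer_,
                  resets = NA_integer_, postResetTarget = NA_integer_,
                  postResetNontarget = NA_integer_, noPellets = NA)
  out <- data.frame(
    session_id = log@sessionId, subject_id = log@subjectId,
    group = log@group, schedule = log@schedule@kind,
    total_pokes = nrow(p), target_pokes = sum(p$target),
    nontarget_pokes = sum(!p$target),
    accuracy_overall = acc$overall,
    pellets = eff$pellets, pellets_per_hour = eff$pelletsPerHour,
    nontarget_per_pellet = eff$nontargetPerPellet,
    criterion_reached = crit@reached,
    criterion_poke_index = crit@pokeIndex,
    criterion_time_s = crit@timeToCriterionS,
    criterion_target_pokes = crit@targetPokes,
    criterion_nontarget_pokes = crit@nontargetPokes,
    first_poke_latency_s = lat$firstPokeLatencyS,
    target_poke_latency_s = lat$targetPokeLatencyS,
    first_pellet_latency_s = lat$firstPelletLatencyS,
    session_duration_s = lat$sessionDurationS,
    breakpoint = bp$breakpoint, first_breakpoint = bp$firstBreakpoint,
    resets = bp$resets, post_reset_target = bp$postResetTarget,
    post_reset_nontarget = bp$postResetNontarget,
    stringsAsFactors = FALSE)
  accBins <- as.data.frame(as.list(acc$bins))
  names(accBins) <- sprintf("acc_bin%d", seq_along(acc$bins))
  cbind(out, accBins)
}

#' Score every session of a simulated cohort
#'
#' Applies [scoreSession()] to each log of a [simulateCohort()] result and
#' row-binds the results.
#'
#' @param cohort result of [simulateCohort()].
#' @param ... passed to [scoreSession()].
#' @return data.frame with one row per subject-session.
#' @export
scoreCohort <- function(cohort, ...) {
  rows <- lapply(cohort, function(subj)
    do.call(rbind, lapply(subj$logs, scoreSession, ...)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
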