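#' @include AllClasses.R
NULL

# Allocate a day's revolutions across 24 hourly bins: `share` in the FAA
# hour(s), the rest spread over the dark phase (feeding onset to lights-on,
# 12 h) with a small light-phase remainder.
.allocateHourly <- function(total, share, config) {
  w <- rep(0.02, 24)               # light-phase trickle
  darkH <- (floor(config@feedingStartH):23)
  w[darkH + 1L] <- 1
  faaH <- floor(config@faaStartH):(ceiling(config@faaEndH) - 1L)
  w[faaH + 1L] <- 0
  w <- w / sum(w) * (1 - share)
  w[faaH + 1L] <- share / length(faaH)
  revs <- floor(total * w)
  # hand the rounding remainder to the first dark hour
  revs[darkH[1] + 1L] <- revs[darkH[1] + 1L] + (round(total) - sum(revs))
  pmax(revs, 0)
}

#' Simulate daily records for one ABA rat
#'
#' Generates a baseline phase (weight fluctuating around `bw0`, ad libitum
#' intake stored as absent, wheel running at `runDrive`) followed by an ABA
#' phase under the toy energy-balance model
#' `BW(d+1) = BW(d) + intakeGain * intake(d) - runCost * revs(d)/1000 -
#' basalLoss + noise`, with running scaled by the restriction multiplier
#' from ABA day 1 and intake adapting across days. Hourly running is
#' allocated with the phase's `faaShare` in the food-anticipation hour.
#' The simulation stops on the day weight falls below the susceptibility
#' threshold (that day's record is kept) or after `maxAbaDays`. Weight is
#' measured once daily immediately before the feeding window. The
#' generator is a synthetic stand-in; only the downstream classification
#' claims fidelity to the paradigm's definitions.
#'
#' @param params a [RatSimParams-class].
#' @param config an [AbaConfig-class].
#' @param seed integer seed (same seed, same table).
#' @param subjectId subject label.
#' @return data.frame of daily records in the [readAbaDaily()] layout.
#' @examples
#' d <- simulateAbaRat(ratSimParams(), abaConfig(), seed = 1)
#' table(d$phase)
#' @export
simulateAbaRat <- function(params, config = abaConfig(), seed,
                           subjectId = "r1") {
  stopifnot(is(params, "RatSimParams"), is(config, "AbaConfig"))
  validObject(params); validObject(config)
  withSeed(seed, .simulateAbaRatCore(params, config, subjectId))
}

.simulateAbaRatCore <- function(params, config, subjectId) {
  nB <- config@baselineDays
  nMax <- nB + config@maxAbaDays
  weight <- numeric(nMax); intake <- rep(NA_real_, nMax)
  revs <- numeric(nMax)
  for (d in seq_len(nB)) {
    weight[d] <- round(params@bw0 + rnorm(1, 0, params@noiseWeight), 1)
    revs[d] <- max(0, rnorm(1, params@runDrive, params@noiseRun))
  }
  baseline <- weight[nB]  # final baseline day anchors %BW
  bw <- baseline
  nDays <- nB
  for (d in seq_len(config@maxAbaDays)) {
    i <- nB + d
    revs[i] <- max(0, rnorm(1, params@runDrive * params@runMult,
                            params@noiseRun))
    intake[i] <- round(max(0, rnorm(1, params@appetite +
                                      params@appetiteSlope * (d - 1),
                                    params@noiseIntake)), 1)
    # first restricted morning: one night of restriction, no intake yet
    bw <- bw + (if (d == 1) 0 else params@intakeGain * intake[i - 1L]) -
      params@runCost * (if (d == 1) revs[i] else revs[i - 1L]) / 1000 -
      params@basalLoss + rnorm(1, 0, params@noiseWeight)
    weight[i] <- round(bw, 1)
    nDays <- i
    # stopping rule uses the recorded (weighed) value, as the lab does
    if (weight[i] < config@susceptibilityFraction * baseline) break
  }
  keep <- seq_len(nDays)
  hourly <- t(vapply(keep, function(i)
    .allocateHourly(revs[i],
                    params@faaShare[if (i <= nB) 1L else 2L], config),
    numeric(24)))
  colnames(hourly) <- ABA_HOUR_COLS
  out <- data.frame(subject_id = subjectId,
                    phase = rep(c("baseline", "aba"),
                                c(nB, nDays - nB)),
                    day = c(seq_len(nB), seq_len(nDays - nB)),
                    body_weight = weight[keep],
                    intake_90min = intake[keep],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(hourly))
}

.baselineWeight <- function(records, config) {
  base <- records[records$phase == "baseline", , drop = FALSE]
  if (nrow(base) < config@baselineDays)
    stopf("incomplete baseline phase (%d of %d days)", nrow(base),
          config@baselineDays)
  base$body_weight[which.max(base$day)]
}

#' Classify the ABA susceptibility outcome
#'
#' Applies the susceptibility criterion to a rat's daily records: percent
#' body weight is taken relative to the final baseline day's weight, and a
#' rat is susceptible iff any ABA day within the protocol window falls
#' below the susceptibility fraction (default 80%); the first such day is
#' the removal day, after which no records may exist. Days with percent
#' weight above the maintenance fraction (default 85%) are counted as
#' `daysAbove85`.
#'
#' @param records data.frame of daily records (validated by
#'   [validateAbaDaily()]) for one subject.
#' @param config an [AbaConfig-class].
#' @return An [AbaOutcome-class] with the classification fields set;
#'   phenotype fields are completed by [phenotypeMetrics()].
#' @examples
#' recs <- simulateAbaRat(ratSimParams(), abaConfig(), seed = 1)
#' classifyOutcome(recs, abaConfig())
#' @export
classifyOutcome <- function(records, config = abaConfig()) {
  stopifnot(is(config, "AbaConfig"))
  records <- validateAbaDaily(records)
  .classifyCore(records, config)
}

.classifyCore <- function(records, config) {
  if (length(unique(records$subject_id)) != 1L)
    stopf("classifyOutcome expects records for a single subject")
  baseline <- .baselineWeight(records, config)
  aba <- records[records$phase == "aba", , drop = FALSE]
  pct <- 100 * aba$body_weight / baseline
  inWindow <- aba$day <= config@maxAbaDays
  below <- which(pct < 100 * config@susceptibilityFraction & inWindow)
  susceptible <- length(below) > 0L
  removalDay <- if (susceptible) as.integer(aba$day[below[1]]) else
    NA_integer_
  if (susceptible && any(aba$day > removalDay))
    stopf("records continue after removal day %d", removalDay)
  new("AbaOutcome", subjectId = records$subject_id[1],
      susceptible = susceptible, removalDay = removalDay,
      daysAbove85 = sum(pct > 100 * config@maintenanceFraction & inWindow),
      meanDailyPctLoss = mean(-diff(c(100, pct))),
      lowestPctBw = if (nrow(aba)) min(pct) else NA_real_,
      faaChange = NA_real_, faaBaseline = NA_real_, faaAba = NA_real_,
      faaAbsBaseline = NA_real_, faaAbsAba = NA_real_,
      meanIntake7d = NA_real_, baselineRevs = NA_real_,
      abaRevs = NA_real_)
}

.faaFractions <- function(records, config) {
  faaH <- floor(config@faaStartH):(ceiling(config@faaEndH) - 1L)
  revs <- as.matrix(records[, ABA_HOUR_COLS])
  total <- rowSums(revs)
  faa <- rowSums(revs[, faaH + 1L, drop = FALSE])
  frac <- ifelse(total > 0, faa / total, NA_real_)  # zero-running: absent
  list(frac = frac, abs = faa, total = total)
}

#' Complete the ABA phenotype metrics
#'
#' Fills the remaining [AbaOutcome-class] fields from the daily records:
#' the food-anticipatory fraction of each day's running (revolutions in
#' the FAA window over the day's total; absent on zero-running days), its
#' ABA-minus-baseline change, absolute FAA revolutions by phase, mean
#' intake over the first 7 ABA days (or until removal), and phase means of
#' daily revolutions.
#'
#' @param records data.frame of daily records for one subject.
#' @param config an [AbaConfig-class].
#' @return A completed [AbaOutcome-class].
#' @export
phenotypeMetrics <- function(records, config = abaConfig()) {
  stopifnot(is(config, "AbaConfig"))
  records <- validateAbaDaily(records)
  .phenotypeCore(records, config)
}

.phenotypeCore <- function(records, config) {
  out <- .classifyCore(records, config)
  base <- records[records$phase == "baseline", , drop = FALSE]
  aba <- records[records$phase == "aba", , drop = FALSE]
  fB <- .faaFractions(base, config)
  fA <- .faaFractions(aba, config)
  out@faaBaseline <- mean(fB$frac, na.rm = TRUE)
  out@faaAba <- mean(fA$frac, na.rm = TRUE)
  out@faaChange <- out@faaAba - out@faaBaseline
  out@faaAbsBaseline <- mean(fB$abs)
  out@faaAbsAba <- mean(fA$abs)
  first7 <- aba[aba$day <= 7L, , drop = FALSE]
  out@meanIntake7d <- if (nrow(first7)) mean(first7$intake_90min) else
    NA_real_
  out@baselineRevs <- mean(fB$total)
  out@abaRevs <- mean(fA$total)
  validObject(out)
  out
}

#' Simulate an ABA cohort and tabulate outcomes
#'
#' Convenience wrapper: simulates `n` rats with per-rat seeds derived from
#' `seed`, classifies each, and returns a data.frame of outcome fields
#' (one row per rat) plus the daily records in an attribute-free list.
#'
#' A treated cohort with heterogeneous response can be generated as a
#' two-component mixture: each rat is a "responder" with probability
#' `respFraction` and then draws its trajectory from `respParams`
#' (typically a lower restriction multiplier on running and a steeper
#' appetite slope), reproducing the bimodal susceptible/resistant split.
#'
#' @param params a [RatSimParams-class] shared by all (non-responder) rats.
#' @param n number of rats.
#' @param config an [AbaConfig-class].
#' @param seed master seed.
#' @param label group label used in subject ids.
#' @param respParams optional [RatSimParams-class] for the responder
#'   subgroup.
#' @param respFraction probability that a rat is a responder (default 0).
#' @return List with `outcomes` (data.frame) and `records` (named list of
#'   daily data.frames).
#' @export
simulateAbaCohort <- function(params, n, config = abaConfig(), seed = 1,
                              label = "grp", respParams = NULL,
                              respFraction = 0) {
  recs <- list(); rows <- list()
  isResp <- withSeed(deriveSeed(seed, 0L),
                     runif(n) < respFraction & !is.null(respParams))
  for (i in seq_len(n)) {
    sid <- sprintf("%s_%02d", label, i)
    p <- if (isResp[i]) respParams else params
    d <- simulateAbaRat(p, config, deriveSeed(seed, i), subjectId = sid)
    o <- .phenotypeCore(d, config)  # generator output is valid by construction
    recs[[sid]] <- d
    rows[[sid]] <- data.frame(
      subject_id = sid, group = label, susceptible = o@susceptible,
      removal_day = o@removalDay, days_above_85 = o@daysAbove85,
      mean_daily_pct_loss = o@meanDailyPctLoss,
      lowest_pct_bw = o@lowestPctBw, faa_change = o@faaChange,
      faa_baseline = o@faaBaseline, faa_aba = o@faaAba,
      mean_intake_7d = o@meanIntake7d, baseline_revs = o@baselineRevs,
      aba_revs = o@abaRevs, stringsAsFactors = FALSE)
  }
  outcomes <- do.call(rbind, rows)
  rownames(outcomes) <- NULL
  list(outcomes = outcomes, records = recs)
}
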