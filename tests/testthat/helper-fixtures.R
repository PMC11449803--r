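# Fixture builders and independent oracles shared across test files.

# Build an EventLog from poke kinds at integer-second spacing (or explicit
# times), filling the requirement column with the schedule's fixed ratio.
pokeLog <- function(kinds, spec, times = seq_along(kinds),
                    requirement = NULL, ...) {
  req <- if (!is.null(requirement)) requirement
         else if (spec@kind == "FR") rep(spec@ratio, length(kinds))
         else rep(NA_integer_, length(kinds))
  req[kinds == "pellet_removed"] <- NA_integer_
  eventLog(data.frame(timestamp = times, kind = kinds, requirement = req),
           spec, ...)
}

# Random poke-only log on an FR5/left schedule; pTarget controls accuracy.
randomPokeLog <- function(n, pTarget = 0.5,
                          spec = scheduleSpec("FR", ratio = 5,
                                              sessionDurationS = n + 1)) {
  kinds <- ifelse(runif(n) < pTarget, "poke_left", "poke_right")
  pokeLog(kinds, spec, times = seq_len(n))
}

# Exhaustive moving-window criterion oracle: for every poke k, count target
# pokes among the last min(k, window) pokes by explicit slicing.
bruteCriterion <- function(target, window = 100L, threshold = 80L) {
  for (k in seq_along(target)) {
    lo <- max(1L, k - window + 1L)
    if (sum(target[lo:k]) >= threshold) return(k)
  }
  NA_integer_
}

# Textbook pooled-variance two-sample t statistic and two-sided p.
textbookT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, df = na + nb - 2, p = 2 * pt(-abs(tt), na + nb - 2))
}

# Daily ABA records for one subject from a given %BW series (ABA phase),
# with a flat 7-day baseline and a configurable hourly running pattern.
mkAbaRecords <- function(pctSeries, baselineW = 250, intake = 8,
                         hourly = NULL, subject = "r1") {
  nB <- 7L
  if (is.null(hourly)) {
    hourly <- rep(100, 24)  # uniform running over 24 h
  }
  mk <- function(phase, day, bw) {
    r <- as.list(hourly)
    names(r) <- sprintf("rev_h%02d", 0:23)
    as.data.frame(c(list(subject_id = subject, phase = phase, day = day,
                         body_weight = bw,
                         intake_90min = if (phase == "aba") intake
                                        else NA_real_), r))
  }
  rows <- c(lapply(seq_len(nB), function(d) mk("baseline", d, baselineW)),
            lapply(seq_along(pctSeries), function(d)
              mk("aba", d, baselineW * pctSeries[d] / 100)))
  do.call(rbind, rows)
}

# Small cell table with exact class counts in one section.
mkCellSection <- function(nDouble, nExcl1a, nExcl2a, nNeg = 0,
                          animal = "a1", region = "IL", section = "s1",
                          distance = 500) {
  n <- nDouble + nExcl1a + nExcl2a + nNeg
  data.frame(
    animal_id = animal, region = region, section_id = section,
    distance_um = rep(distance, n),
    htr1a_count = c(rep(2L, nDouble), rep(3L, nExcl1a),
                    rep(0L, nExcl2a + nNeg)),
    htr2a_count = c(rep(5L, nDouble), rep(0L, nExcl1a),
                    rep(4L, nExcl2a), rep(0L, nNeg)),
    stringsAsFactors = FALSE)
}
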