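#' @include AllClasses.R
NULL

## Native event-log layout: one CSV row per event with columns
## (session_id, subject_id, group, schedule, timestamp_s, event,
## requirement). The schedule column is a lossless '|'-separated
## serialisation of the ScheduleSpec. Timestamps are stored in seconds from
## device access at 0.1 s resolution (the device logs at roughly second
## resolution; sub-second ties are resolved by row order).

NATIVE_COLS <- c("session_id", "subject_id", "group", "schedule",
                 "timestamp_s", "event", "requirement")

.serializeSchedule <- function(spec) {
  paste(spec@kind, spec@ratio, spec@rangeLow, spec@rangeHigh,
        format(spec@prRate, digits = 15), format(spec@prScale, digits = 15),
        spec@targetSide, format(spec@inactivityResetS, digits = 15),
        format(spec@sessionDurationS, digits = 15), sep = "|")
}

.parseSchedule <- function(s) {
  f <- strsplit(s, "|", fixed = TRUE)[[1]]
  if (length(f) != 9L) stopf("malformed schedule field '%s'", s)
  scheduleSpec(kind = f[1], ratio = as.integer(f[2]),
               rangeLow = as.integer(f[3]), rangeHigh = as.integer(f[4]),
               prRate = as.numeric(f[5]), prScale = as.numeric(f[6]),
               targetSide = f[7], inactivityResetS = as.numeric(f[8]),
               sessionDurationS = as.numeric(f[9]))
}

.checkHeader <- function(header, expected, path) {
  if (anyDuplicated(header))
    stopf("duplicate header column(s) in %s: %s", path,
          paste(unique(header[duplicated(header)]), collapse = ", "))
  missing <- setdiff(expected, header)
  if (length(missing))
    stopf("missing header column(s) in %s: %s", path,
          paste(missing, collapse = ", "))
}

#' Read an operant event log
#'
#' Reads a single-session event-log CSV into a validated
#' [EventLog-class]. Two dialects are supported: the package's native
#' layout (see Details) and a `fed3` mapper for classic FED3 library
#' exports, whose cumulative per-row counts are converted to discrete
#' events by differencing.
#'
#' @details The native layout has one row per event and columns
#' `session_id, subject_id, group, schedule, timestamp_s, event,
#' requirement`. Unknown event codes are rejected; timestamps must be
#' sorted (ties by row order). The `fed3` dialect expects columns
#' `MM:DD:YYYY hh:mm:ss`, `Event`, `Active_Poke`, `Left_Poke_Count`,
#' `Right_Poke_Count` and `Pellet_Count`; timestamps are normalised to
#' seconds from the first row, and an `FR` column (when present) supplies
#' the requirement in force. The mapping follows the public FED3 library's
#' documented columns and is a dialect, not ground truth.
#'
#' @param path CSV file path.
#' @param dialect `"native"` (default) or `"fed3"`.
#' @param schedule for the `fed3` dialect only: the [ScheduleSpec-class] in
#'   force (native files carry their own schedule).
#' @return A validated [EventLog-class].
#' @seealso [writeEventLog()]
#' @export
readEventLog <- function(path, dialect = c("native", "fed3"),
                         schedule = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "native") .readNativeLog(path) else
    .readFed3Log(path, schedule)
}

.readNativeLog <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  .checkHeader(header, NATIVE_COLS, path)
  d <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(timestamp_s = "numeric",
                               requirement = "integer"))
  if (!nrow(d))
    stopf("event-log file %s has no rows; session metadata unrecoverable",
          path)
  if (length(unique(d$session_id)) > 1L)
    stopf("%s contains multiple sessions; one session per file", path)
  bad <- setdiff(unique(d$event), EVENT_KINDS)
  if (length(bad) && !identical(bad, "session_marker"))
    stopf("unknown event code(s) in %s: %s", path,
          paste(setdiff(bad, "session_marker"), collapse = ", "))
  if (is.unsorted(d$timestamp_s))
    stopf("timestamps not sorted in %s; first offending row %d", path,
          which(diff(d$timestamp_s) < 0)[1] + 1L)
  # normalise to seconds from the first row's access marker
  keep <- d$event != "session_marker"
  t0 <- if (any(!keep)) d$timestamp_s[!keep][1] else 0
  ev <- d[keep, , drop = FALSE]
  eventLog(data.frame(timestamp = ev$timestamp_s - t0, kind = ev$event,
                      requirement = ev$requirement,
                      stringsAsFactors = FALSE),
           .parseSchedule(d$schedule[1]),
           sessionId = d$session_id[1], subjectId = d$subject_id[1],
           group = d$group[1])
}

.readFed3Log <- function(path, schedule) {
  if (is.null(schedule))
    stopf("the fed3 dialect requires a `schedule` (files carry none)")
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  tcol <- grep("MM:DD:YYYY", names(d), value = TRUE)
  need <- c("Event", "Left_Poke_Count", "Right_Poke_Count", "Pellet_Count")
  .checkHeader(names(d), need, path)
  if (!length(tcol)) stopf("missing timestamp column in %s", path)
  tm <- as.POSIXct(strptime(d[[tcol]], "%m:%d:%Y %H:%M:%S", tz = "UTC"))
  if (anyNA(tm)) stopf("unparseable timestamp(s) in %s", path)
  secs <- as.numeric(difftime(tm, tm[1], units = "secs"))
  if (is.unsorted(secs))
    stopf("timestamps not sorted in %s; first offending row %d", path,
          which(diff(secs) < 0)[1] + 1L)
  req <- if ("FR" %in% names(d)) suppressWarnings(as.integer(d$FR))
         else rep(NA_integer_, nrow(d))

  # cumulative counts -> discrete events by differencing
  ts <- numeric(0); kd <- character(0); rq <- integer(0)
  addEvents <- function(counts, kind) {
    inc <- diff(c(0L, as.integer(counts)))
    if (any(inc < 0))
      stopf("cumulative column for %s decreases in %s", kind, path)
    rows <- rep.int(seq_along(inc), pmax(inc, 0L))
    ts <<- c(ts, secs[rows]); kd <<- c(kd, rep(kind, length(rows)))
    rq <<- c(rq, req[rows])
  }
  addEvents(d$Left_Poke_Count, "poke_left")
  addEvents(d$Right_Poke_Count, "poke_right")
  addEvents(d$Pellet_Count, "pellet_dispensed")
  if (schedule@kind %in% c("EXT", "FREE")) rq[] <- NA_integer_
  else if (identical(schedule@kind, "FR") && anyNA(rq))
    rq[is.na(rq)] <- schedule@ratio
  ord <- order(ts)  # stable: dispenses keep their within-timestamp order
  eventLog(data.frame(timestamp = ts[ord], kind = kd[ord],
                      requirement = rq[ord], stringsAsFactors = FALSE),
           schedule, sessionId = basename(path), subjectId = "unknown",
           group = "unknown")
}

#' Write an operant event log
#'
#' Writes an [EventLog-class] in the native CSV layout. Timestamps are
#' written at 0.1 s resolution (the device's effective logging resolution);
#' column order and number formats are fixed, so two writes of the same log
#' are byte-identical. An empty log writes a header plus a single
#' `session_marker` row carrying the session metadata.
#'
#' @param log an [EventLog-class].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @seealso [readEventLog()]
#' @export
writeEventLog <- function(log, path) {
  stopifnot(is(log, "EventLog"))
  validObject(log)
  ev <- log@events
  sched <- .serializeSchedule(log@schedule)
  lines <- paste(NATIVE_COLS, collapse = ",")
  meta <- paste(log@sessionId, log@subjectId, log@group, sched, sep = ",")
  rows <- c(sprintf("%s,0.0,session_marker,", meta),
            if (nrow(ev))
              sprintf("%s,%.1f,%s,%s", meta, ev$timestamp, ev$kind,
                      ifelse(is.na(ev$requirement), "",
                             as.character(ev$requirement))))
  ok <- tryCatch({
    writeLines(c(lines, rows), path); TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write event log to %s", path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# ABA daily records
# ---------------------------------------------------------------------------

ABA_HOUR_COLS <- sprintf("rev_h%02d", 0:23)
ABA_COLS <- c("subject_id", "phase", "day", "body_weight", "intake_90min",
              ABA_HOUR_COLS)

#' Read daily ABA records
#'
#' Reads a CSV of per-subject-day ABA records (body weight, 90-min intake,
#' hourly wheel revolutions in 24 columns `rev_h00`..`rev_h23`) and returns
#' a validated data.frame sorted by subject, phase (baseline before aba)
#' and day. Intake must be absent (empty/`NA`) on baseline rows — baseline
#' feeding is ad libitum — and day numbering must be contiguous from 1
#' within each subject and phase.
#'
#' @param path CSV file path.
#' @return data.frame with columns `subject_id`, `phase`
#'   (`baseline`/`aba`), `day`, `body_weight`, `intake_90min`, and the 24
#'   hourly revolution columns.
#' @seealso [writeAbaDaily()], [simulateAbaRat()]
#' @export
readAbaDaily <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  .checkHeader(header, ABA_COLS, path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  validateAbaDaily(d)
}

#' Validate a daily ABA record table
#'
#' Applies the [readAbaDaily()] invariants to an in-memory table and
#' returns it sorted by subject, phase and day.
#'
#' @param d data.frame in the [readAbaDaily()] layout.
#' @return The validated, sorted data.frame.
#' @export
validateAbaDaily <- function(d) {
  missing <- setdiff(ABA_COLS, names(d))
  if (length(missing))
    stopf("missing column(s): %s", paste(missing, collapse = ", "))
  if (any(!d$phase %in% c("baseline", "aba")))
    stopf("phase must be 'baseline' or 'aba'")
  if (any(is.na(d$body_weight)) || any(d$body_weight <= 0))
    stopf("body weights must be positive")
  if (any(d$phase == "baseline" & !is.na(d$intake_90min)))
    stopf("baseline rows must not carry intake (ad libitum feeding)")
  if (any(d$phase == "aba" & is.na(d$intake_90min)))
    stopf("aba rows must carry a 90-min intake")
  for (col in ABA_HOUR_COLS) d[[col]] <- as.numeric(d[[col]])
  d$day <- as.integer(d$day)
  revs <- as.matrix(d[, ABA_HOUR_COLS])
  if (anyNA(revs) || any(revs < 0))
    stopf("hourly revolutions must be non-negative and complete (24 bins)")
  d$phase <- factor(d$phase, levels = c("baseline", "aba"))
  d <- d[order(d$subject_id, d$phase, d$day), , drop = FALSE]
  for (sid in unique(d$subject_id)) {
    for (ph in c("baseline", "aba")) {
      days <- d$day[d$subject_id == sid & d$phase == ph]
      if (length(days) && !identical(as.integer(days),
                                     seq_len(length(days))))
        stopf("subject %s has non-contiguous %s day numbering", sid, ph)
    }
  }
  d$phase <- as.character(d$phase)
  rownames(d) <- NULL
  d
}

#' Write daily ABA records
#'
#' Deterministic CSV writer for the [readAbaDaily()] layout.
#'
#' @param d validated ABA daily data.frame.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeAbaDaily <- function(d, path) {
  d <- validateAbaDaily(d)
  write.csv(d[, ABA_COLS], path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Per-cell transcript-count tables
# ---------------------------------------------------------------------------

CELL_COLS <- c("animal_id", "region", "section_id", "distance_um",
               "htr1a_count", "htr2a_count")
REGIONS <- c("PrL", "IL")

#' Read a per-cell transcript-count table
#'
#' Reads a CSV with one row per segmented cell (as exported by
#' CellProfiler/Imaris-style pipelines): animal, mPFC subregion (`PrL` or
#' `IL`), section, distance from the Layer I midline in micrometres, and
#' Htr1a/Htr2a puncta counts. Counts are coerced to integer only when
#' exactly integral; negative counts and unknown regions are rejected.
#'
#' @param path CSV file path.
#' @return Validated data.frame with the columns above.
#' @seealso [writeCellTable()], [classifyCell()]
#' @export
readCellTable <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  .checkHeader(header, CELL_COLS, path)
  validateCellTable(read.csv(path, stringsAsFactors = FALSE))
}

#' Validate a per-cell transcript-count table
#'
#' @param d data.frame in the [readCellTable()] layout.
#' @return The validated data.frame (counts as integers).
#' @export
validateCellTable <- function(d) {
  missing <- setdiff(CELL_COLS, names(d))
  if (length(missing))
    stopf("missing column(s): %s", paste(missing, collapse = ", "))
  bad <- setdiff(unique(d$region), REGIONS)
  if (length(bad))
    stopf("unknown region(s): %s", paste(bad, collapse = ", "))
  if (anyNA(d$distance_um) || any(d$distance_um < 0))
    stopf("distance_um must be non-negative")
  for (col in c("htr1a_count", "htr2a_count")) {
    x <- d[[col]]
    if (anyNA(x) || any(x < 0)) stopf("%s must be non-negative", col)
    if (any(x != round(x)))
      stopf("%s contains non-integral count(s), e.g. %s", col,
            format(x[x != round(x)][1]))
    d[[col]] <- as.integer(round(x))
  }
  rownames(d) <- NULL
  d
}

#' Write a per-cell transcript-count table
#'
#' @param d validated cell table data.frame.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeCellTable <- function(d, path) {
  d <- validateCellTable(d)
  write.csv(d[, CELL_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Run configuration
# ---------------------------------------------------------------------------

#' Read a YAML run configuration
#'
#' Parses a single YAML configuration (paths, dialect, schedule parameters,
#' seeds). A `schedule:` mapping such as
#' `schedule: {kind: PR, pr_rate: 0.2, pr_scale: 5, target: left}` is
#' converted to a [ScheduleSpec-class] under `$schedule`.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$schedule)) cfg$schedule <- scheduleFromConfig(cfg$schedule)
  cfg
}

#' Build a schedule from a configuration mapping
#'
#' @param x named list with `kind` and optional fields `ratio`,
#'   `range_low`, `range_high`, `pr_rate`, `pr_scale`, `target`,
#'   `inactivity_reset_s`, `session_duration_s`.
#' @return A [ScheduleSpec-class].
#' @export
scheduleFromConfig <- function(x) {
  scheduleSpec(kind = x$kind,
               ratio = x$ratio %||% 1,
               rangeLow = x$range_low %||% 1,
               rangeHigh = x$range_high %||% 1,
               prRate = x$pr_rate %||% 0.2,
               prScale = x$pr_scale %||% 5,
               targetSide = x$target %||% "left",
               inactivityResetS = x$inactivity_reset_s %||% 600,
               sessionDurationS = x$session_duration_s %||% 10800)
}
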