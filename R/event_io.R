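#' Event logs
#'
#' An event log is a data frame of timestamped binary sensor events, the raw
#' material of ambient activity monitoring. Columns:
#' \describe{
#'   \item{time}{`POSIXct` (UTC, second resolution), non-decreasing.}
#'   \item{sensor}{canonical sensor id, e.g. `"M004"`.}
#'   \item{value}{one of `"ON"`, `"OFF"`, `"OPEN"`, `"CLOSE"`.}
#'   \item{activity}{activity name or `NA` (only on annotated rows).}
#'   \item{marker}{`"begin"`, `"end"` or `NA`; present only with an activity.}
#' }
#'
#' @param time POSIXct vector.
#' @param sensor character vector of sensor ids.
#' @param value character vector of sensor values.
#' @param activity optional character vector of activity annotations.
#' @param marker optional character vector of begin/end markers.
#' @return An object of class `event_log` (a data frame).
#' @export
event_log <- function(time = as.POSIXct(character(), tz = "UTC"),
                      sensor = character(), value = character(),
                      activity = NA_character_, marker = NA_character_) {
  n <- length(time)
  df <- data.frame(
    time = as.POSIXct(time, tz = "UTC"),
    sensor = if (n) canonical_sensor(sensor) else character(),
    value = as.character(value),
    activity = rep_len(as.character(activity), n),
    marker = rep_len(as.character(marker), n),
    stringsAsFactors = FALSE
  )
  validate_event_log(df)
  class(df) <- c("event_log", "data.frame")
  df
}

ALLOWED_VALUES <- c("ON", "OFF", "OPEN", "CLOSE")

validate_event_log <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(!df$value %in% ALLOWED_VALUES)) {
    stop("event value(s) outside {ON, OFF, OPEN, CLOSE}: ",
         paste(unique(setdiff(df$value, ALLOWED_VALUES)), collapse = ", "))
  }
  if (any(!is.na(df$marker) & is.na(df$activity))) {
    stop("begin/end marker present without an activity name")
  }
  if (any(!df$marker %in% c(NA, "begin", "end"))) {
    stop("marker must be 'begin' or 'end'")
  }
  if (is.unsorted(df$time)) stop("event timestamps must be non-decreasing")
  invisible(df)
}

as_event_log <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("event_log", "data.frame")
  df
}

#' Read a CASAS-style plain-text sensor log
#'
#' Parses the whitespace-separated dialect used by public CASAS deployments:
#' `date time sensor value [activity begin|end]`, e.g.
#' `2010-11-04 05:40:51 M004 ON Bed_to_Toilet begin`.
#'
#' Real deployment logs occasionally contain timestamp inversions; by default
#' these are repaired by a stable sort with a warning. With `strict = TRUE`
#' an inversion raises an error instead.
#'
#' @param path path to the log file.
#' @param strict error (rather than warn + stable sort) on out-of-order
#'   timestamps.
#' @return An `event_log`.
#' @export
read_casas_log <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(event_log())
  toks <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(toks)
  bad <- which(nf != 4L & nf != 6L)
  if (length(bad)) {
    stop("malformed log line ", bad[1], ": expected 4 or 6 fields, got ",
         nf[bad[1]], " (", lines[bad[1]], ")")
  }
  m <- matrix("", nrow = length(toks), ncol = 6)
  for (i in seq_along(toks)) m[i, seq_len(nf[i])] <- toks[[i]]
  tm <- as.POSIXct(paste(m[, 1], m[, 2]), tz = "UTC",
                   format = "%Y-%m-%d %H:%M:%S")
  if (anyNA(tm)) {
    stop("malformed log line ", which(is.na(tm))[1], ": unparseable timestamp")
  }
  activity <- ifelse(nf == 6L, m[, 5], NA_character_)
  marker <- ifelse(nf == 6L, m[, 6], NA_character_)
  if (any(!is.na(marker) & !marker %in% c("begin", "end"))) {
    i <- which(!is.na(marker) & !marker %in% c("begin", "end"))[1]
    stop("malformed log line ", i, ": marker must be 'begin' or 'end'")
  }
  df <- data.frame(time = tm, sensor = canonical_sensor(m[, 3]),
                   value = m[, 4], activity = activity, marker = marker,
                   stringsAsFactors = FALSE)
  if (is.unsorted(df$time)) {
    if (strict) stop("out-of-order timestamps in ", path)
    warning("out-of-order timestamps in ", path, "; applying stable sort")
    df <- df[order(df$time, method = "radix"), , drop = FALSE]
  }
  validate_event_log(df)
  as_event_log(df)
}

#' Write an event log in CASAS plain-text format
#'
#' @param log an `event_log`.
#' @param path output file path.
#' @return `invisible(path)`. The written file re-reads to an equal log.
#' @export
write_casas_log <- function(log, path) {
  validate_event_log(log)
  if (nrow(log) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  ann <- ifelse(is.na(log$activity), "",
                paste0(" ", log$activity, " ", log$marker))
  lines <- paste0(format(log$time, "%Y-%m-%d %H:%M:%S", tz = "UTC"), " ",
                  log$sensor, " ", log$value, ann)
  writeLines(lines, path)
  invisible(path)
}

#' Pair begin/end annotations into activity instances
#'
#' Scans the log for `begin`/`end` markers and pairs them per activity name
#' in order of appearance. Instances of different activities may interleave
#' (a night toilet visit inside a sleeping span); instances of the same name
#' may not.
#'
#' @param log an `event_log`.
#' @return A data frame with one row per instance, ordered by start time:
#'   `activity`, `start`, `end` (POSIXct) and `start_idx`, `end_idx`
#'   (row indices of the begin/end events in `log`).
#' @export
annotate_activities <- function(log) {
  empty <- data.frame(activity = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      start_idx = integer(), end_idx = integer(),
                      stringsAsFactors = FALSE)
  ann <- which(!is.na(log$marker))
  if (length(ann) == 0) return(empty)
  out <- list()
  for (act in unique(log$activity[ann])) {
    rows <- ann[log$activity[ann] == act]
    mk <- log$marker[rows]
    begins <- rows[mk == "begin"]
    ends <- rows[mk == "end"]
    if (length(begins) != length(ends)) {
      orphan <- if (length(begins) > length(ends)) "begin" else "end"
      stop("unmatched '", orphan, "' marker for activity '", act, "'")
    }
    if (length(begins) && any(ends < begins)) {
      stop("unmatched 'end' marker for activity '", act,
           "' (end precedes begin)")
    }
    out[[act]] <- data.frame(activity = act,
                             start = log$time[begins], end = log$time[ends],
                             start_idx = begins, end_idx = ends,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$start_idx, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-event activity labels
#'
#' Expands paired begin/end annotations into a label for every event: events
#' at indices within an instance's begin..end range take its activity name,
#' all others `NA`. When instances of different activities interleave, the
#' later-starting instance wins on the overlap.
#'
#' @param log an `event_log`.
#' @return character vector of length `nrow(log)`.
#' @export
event_activities <- function(log) {
  lab <- rep(NA_character_, nrow(log))
  inst <- annotate_activities(log)
  if (nrow(inst)) {
    for (i in seq_len(nrow(inst))) {
      lab[inst$start_idx[i]:inst$end_idx[i]] <- inst$activity[i]
    }
  }
  lab
}
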