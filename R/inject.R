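#' @name anomaly-injection
#' @title Simulated dementia-related anomalies
#'
#' @description
#' Two generators emulate the behavioural disruptions of cognitive decline:
#'
#' * **activity-level** ([inject_activity_anomalies()]): a whole activity
#'   instance is repeated at an abnormal time of day — cooking or eating in
#'   the middle of the night (sleep-cycle degeneration), or an extra daytime
#'   activity inserted inside another one (frequency anomaly);
#' * **sub-activity-level** ([inject_subactivity_anomalies()]): within an
#'   instance, a characteristic sensor is triggered abnormally often —
#'   e.g. repeatedly re-activating the desk sensor while confused at the
#'   computer.
#'
#' Both return the modified log plus ground-truth records sufficient for
#' window-level evaluation: a window is abnormal iff at least one injected
#' event falls inside it (see [windows_truth()]).
NULL

#' Default insertion contexts for activity-level anomalies
#'
#' Meal preparation, eating, work, washing dishes and leaving/entering home
#' are re-inserted into daytime sequences (frequency anomalies); relaxing,
#' eating, bed-to-toilet and respirating are inserted into sleeping spans
#' (sleep-disorder anomalies).
#'
#' @return named character vector mapping activity name to context
#'   (`"day"` or `"sleeping"`).
#' @export
default_activity_contexts <- function() {
  c(Meal_Preparation = "day", Eating = "day", Work = "day",
    Wash_Dishes = "day", Leave_Home = "day", Enter_Home = "day",
    Relaxing = "sleeping", Eating_Night = "sleeping",
    Bed_to_Toilet = "sleeping", Respirate = "sleeping")
}

anomaly_record <- function(kind, activity = NA_character_,
                           sensor = NA_character_, span, times,
                           source = NA_integer_) {
  structure(list(kind = kind, activity = activity, sensor = sensor,
                 span_start = span[1], span_end = span[2],
                 times = times, event_idx = integer(), source = source),
            class = "anomaly_record")
}

# Re-sort an augmented log and fill each record's event indices in the
# output. `src` tags rows: 0 = original, i > 0 = inserted by record i.
finalize_injection <- function(df, src, records) {
  ord <- order(df$time, method = "radix")   # stable: originals stay a subsequence
  df <- df[ord, , drop = FALSE]
  src <- src[ord]
  for (i in seq_along(records)) records[[i]]$event_idx <- which(src == i)
  validate_event_log(df)
  structure(list(log = as_event_log(df), records = records),
            class = "injection_result")
}

#' Inject whole-activity anomalies (repeated activities at abnormal times)
#'
#' For each of `n` injections a donor instance of a randomly chosen activity
#' from `insert_activities` is copied and inserted at a context-sanctioned
#' abnormal position: inside a sleeping span for the sleep-disorder set,
#' inside a different daytime activity otherwise. The donor block is rigidly
#' translated to the insertion time and linearly compressed if it would
#' overrun the host span, preserving intra-activity order and frequency.
#'
#' @param log an annotated `event_log`.
#' @param insert_activities activity names eligible for insertion; each needs
#'   at least one donor instance in `donor_log`.
#' @param contexts named map from activity name to `"day"` or `"sleeping"`
#'   (see [default_activity_contexts()]). An `"<name>_Night"` alias lets the
#'   same activity appear in both context sets.
#' @param n number of insertions.
#' @param seed integer seed.
#' @param donor_log log the donor instances are copied from (defaults to
#'   `log` itself; pass the training log to keep test-day donors out).
#' @param sleeping_activity name of the sleeping class.
#' @return An `injection_result`: list with `log` (time-sorted `event_log`)
#'   and `records` (list of `anomaly_record`s, one per insertion).
#' @export
inject_activity_anomalies <- function(log,
                                      insert_activities = names(default_activity_contexts()),
                                      contexts = default_activity_contexts(),
                                      n = 1, seed = 1L, donor_log = log,
                                      sleeping_activity = "Sleeping") {
  if (n == 0) {
    return(structure(list(log = log, records = list()),
                     class = "injection_result"))
  }
  set.seed(as.integer(seed))
  inst <- annotate_activities(log)
  donors <- annotate_activities(donor_log)
  resolve <- function(a) sub("_Night$", "", a)
  unknown <- setdiff(resolve(insert_activities), donors$activity)
  if (length(unknown)) {
    stop("no donor instance for activity name(s): ",
         paste(unknown, collapse = ", "))
  }
  missing_ctx <- setdiff(insert_activities, names(contexts))
  if (length(missing_ctx)) stop("no insertion context for: ",
                                paste(missing_ctx, collapse = ", "))
  sleep_hosts <- which(inst$activity == sleeping_activity)
  records <- list()
  inserted <- list()
  for (i in seq_len(n)) {
    alias <- sample(insert_activities, 1)
    act <- resolve(alias)
    ctx <- contexts[[alias]]
    hosts <- if (ctx == "sleeping") sleep_hosts
             else which(inst$activity != act & inst$activity != sleeping_activity)
    if (length(hosts) == 0) {
      stop("no ", ctx, " insertion slot available for '", act,
           "' (n exceeds available slots)")
    }
    h <- inst[if (length(hosts) == 1) hosts else sample(hosts, 1), ]
    cand <- which(donors$activity == act)
    d <- donors[if (length(cand) == 1) cand else sample(cand, 1), ]
    block <- donor_log[d$start_idx:d$end_idx, , drop = FALSE]
    dur <- as.numeric(d$end) - as.numeric(d$start)
    host_dur <- as.numeric(h$end) - as.numeric(h$start)
    u <- as.numeric(h$start) + stats::runif(1, 0.05, 0.95) * host_dur
    scale <- min(1, (as.numeric(h$end) - u) / max(dur, 1))
    block$time <- as.POSIXct(round(u + (as.numeric(block$time) -
                                          as.numeric(d$start)) * scale),
                             tz = "UTC", origin = "1970-01-01")
    records[[i]] <- anomaly_record(
      kind = "activity", activity = act,
      span = as.POSIXct(c(u, u + dur * scale), tz = "UTC",
                        origin = "1970-01-01"),
      times = block$time, source = d$start_idx)
    inserted[[i]] <- block
  }
  add <- do.call(rbind, inserted)
  df <- rbind(as.data.frame(log), add)
  src <- c(rep(0L, nrow(log)), rep(seq_len(n), vapply(inserted, nrow, 0L)))
  finalize_injection(df, src, records)
}

#' Default activity-to-characteristic-sensor map for sub-activity anomalies
#'
#' Work is disrupted through the desk sensor M26, eating through the dining
#' sensor M14, meal preparation through the kitchen sensor M18 and
#' bed-to-toilet through the bedroom-exit sensor M4.
#'
#' @return named character vector, activity name -> sensor id.
#' @export
default_subactivity_map <- function() {
  c(Work = "M026", Eating = "M014", Meal_Preparation = "M018",
    Bed_to_Toilet = "M004")
}

#' Inject sub-activity anomalies (abnormal repetition of one sensor)
#'
#' Picks `n` distinct target instances among the activities named in
#' `sensor_map` and inserts the mapped sensor at random interior positions
#' with a random multiplicity in `[min_rep, max_rep]`, turning
#' `s1, s2, ..., sk` into e.g. `s1, M26, s2, s3, M26, ..., sk`. Inserted
#' events take timestamps interpolated between their neighbours, so the
#' original events keep their order and times.
#'
#' @param log an annotated `event_log`.
#' @param sensor_map named map activity -> sensor id
#'   (default [default_subactivity_map()]).
#' @param n number of instances to disrupt.
#' @param min_rep,max_rep bounds of the per-instance repetition count.
#' @param seed integer seed.
#' @return An `injection_result` (see [inject_activity_anomalies()]).
#' @export
inject_subactivity_anomalies <- function(log, sensor_map = default_subactivity_map(),
                                         n = 1, min_rep = 2, max_rep = 6,
                                         seed = 1L) {
  if (n == 0) {
    return(structure(list(log = log, records = list()),
                     class = "injection_result"))
  }
  set.seed(as.integer(seed))
  sensor_map <- stats::setNames(canonical_sensor(sensor_map), names(sensor_map))
  inst <- annotate_activities(log)
  absent <- setdiff(names(sensor_map), inst$activity)
  if (length(absent)) {
    stop("target activity(ies) absent from log: ",
         paste(absent, collapse = ", "))
  }
  # instances need >= 2 events so an interior insertion position exists
  targets <- which(inst$activity %in% names(sensor_map) &
                     inst$end_idx > inst$start_idx)
  if (n > length(targets)) {
    stop("n = ", n, " exceeds the ", length(targets),
         " available target instances")
  }
  chosen <- if (length(targets) == 1) targets else sample(targets, n)
  records <- list()
  inserted <- list()
  for (i in seq_along(chosen)) {
    h <- inst[chosen[i], ]
    sensor <- sensor_map[[h$activity]]
    idx <- h$start_idx:h$end_idx
    times <- as.numeric(log$time[idx])
    reps <- seq.int(min_rep, max_rep)
    m <- reps[sample.int(length(reps), 1)]   # immune to sample()'s length-1 rule
    gaps <- sample.int(length(idx) - 1, m, replace = TRUE)
    t_new <- vapply(gaps, function(g) {
      stats::runif(1, times[g], max(times[g], times[g + 1]))
    }, 0)
    block <- data.frame(
      time = as.POSIXct(round(t_new), tz = "UTC", origin = "1970-01-01"),
      sensor = sensor, value = if (startsWith(sensor, "D")) "OPEN" else "ON",
      activity = NA_character_, marker = NA_character_,
      stringsAsFactors = FALSE)
    block <- block[order(block$time, method = "radix"), , drop = FALSE]
    records[[i]] <- anomaly_record(
      kind = "subactivity", sensor = sensor,
      span = range(block$time), times = block$time, source = h$start_idx)
    inserted[[i]] <- block
  }
  add <- do.call(rbind, inserted)
  df <- rbind(as.data.frame(log), add)
  src <- c(rep(0L, nrow(log)),
           rep(seq_along(chosen), vapply(inserted, nrow, 0L)))
  finalize_injection(df, src, records)
}

#' Window-level ground truth from injection records
#'
#' @param chunks window table from [segment_windows()].
#' @param records list of `anomaly_record`s (from an `injection_result`).
#' @return logical vector: window abnormal iff >= 1 injected event falls in
#'   `[start, end)`.
#' @export
windows_truth <- function(chunks, records) {
  times <- as.numeric(do.call(c, c(lapply(records, `[[`, "times"),
                                   list(as.POSIXct(character(), tz = "UTC")))))
  vapply(seq_len(nrow(chunks)), function(i) {
    any(times >= as.numeric(chunks$start[i]) &
          times < as.numeric(chunks$end[i]))
  }, TRUE)
}

#' Serialise injection records to JSON
#'
#' @param records list of `anomaly_record`s.
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_truth <- function(records, path) {
  lst <- lapply(records, function(r) {
    list(kind = r$kind, activity = r$activity, sensor = r$sensor,
         span_start = format(r$span_start, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
         span_end = format(r$span_end, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
         times = format(r$times, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
         event_idx = r$event_idx, source = r$source)
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
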