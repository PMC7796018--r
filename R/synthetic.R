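#' Activity profile for the routine simulator
#'
#' An activity is simulated as a first-order Markov chain over a small subset
#' of sensors: ambient motion sensors hand off to their physical neighbours
#' as the resident moves, so adjacent-sensor transitions dominate and
#' self-transitions are rare. Inter-event gaps are exponential with the
#' profile's event rate.
#'
#' @param name activity name (single token, e.g. `"Bed_to_Toilet"`).
#' @param sensors character vector of sensor ids involved in the activity.
#' @param transition square row-stochastic matrix over `sensors` (rows sum
#'   to 1), `transition[i, j]` = P(next activation is sensor j | current i).
#' @param rate expected sensor activations per minute (> 0).
#' @param init optional initial-state probabilities (default uniform).
#' @return An object of class `activity_profile`.
#' @export
activity_profile <- function(name, sensors, transition, rate, init = NULL) {
  sensors <- canonical_sensor(sensors)
  k <- length(sensors)
  if (k == 0) stop("activity '", name, "': empty sensor subset")
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(k, k))) {
    stop("activity '", name, "': transition matrix must be ", k, "x", k)
  }
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8)) {
    stop("activity '", name, "': transition rows must be non-negative and sum to 1")
  }
  if (!is.numeric(rate) || rate <= 0) stop("activity '", name, "': rate must be > 0")
  if (is.null(init)) init <- rep(1 / k, k)
  structure(list(name = name, sensors = sensors, transition = transition,
                 rate = rate, init = init / sum(init)),
            class = "activity_profile")
}

# Row-stochastic matrix from a list of named transition weights; rows are
# renormalised so small hand-written weights need not sum exactly to 1.
trans_matrix <- function(sensors, rows) {
  k <- length(sensors)
  m <- matrix(0, k, k, dimnames = list(sensors, sensors))
  for (from in names(rows)) m[from, names(rows[[from]])] <- unlist(rows[[from]])
  m / rowSums(m)
}

#' Daily routine model
#'
#' Bundles the activity profiles with a 24-hour schedule template. The
#' schedule is a data frame of ordered slots (`activity`, `start_min`,
#' `end_min`, minutes from midnight); slots with `activity = NA` are idle
#' (resident away or inactive) and emit no events. Slot boundaries are
#' jittered day-to-day by a Gaussian with `jitter_sd` minutes.
#'
#' @param profiles named list of `activity_profile`s.
#' @param schedule slot data frame as described above.
#' @param registry the `sensor_registry` the profiles draw from.
#' @param jitter_sd day-to-day standard deviation of slot boundaries, minutes.
#' @return An object of class `routine_model`.
#' @export
routine_model <- function(profiles, schedule, registry = default_registry(),
                          jitter_sd = 3) {
  names(profiles) <- vapply(profiles, `[[`, "", "name")
  stopifnot(all(c("activity", "start_min", "end_min") %in% names(schedule)))
  if (any(schedule$end_min <= schedule$start_min)) {
    stop("schedule slots must have positive duration")
  }
  if (any(schedule$start_min[-1] < schedule$end_min[-nrow(schedule)])) {
    stop("schedule slots must not overlap")
  }
  acts <- schedule$activity[!is.na(schedule$activity)]
  missing <- setdiff(acts, names(profiles))
  if (length(missing)) stop("schedule uses unknown activities: ",
                            paste(missing, collapse = ", "))
  for (p in profiles) sensor_index(registry, p$sensors)   # validate subsets
  structure(list(profiles = profiles, schedule = schedule,
                 registry = registry, jitter_sd = jitter_sd),
            class = "routine_model")
}

#' Default single-resident routine model (Aruba-style emulation)
#'
#' A 34-sensor (31 motion + 3 door) single-resident home with the 11
#' activity classes of the Aruba testbed: sleeping, meal preparation,
#' relaxing, eating, work, washing dishes, bed-to-toilet, entering home,
#' leaving home, housekeeping and respirating (breathing exercise).
#'
#' Structure planted on purpose, so downstream stages have known answers:
#' * sleeping alternates between the two bed sensors M002/M003
#'   (P(handoff) >= 0.9), the known top sleeping 2-gram;
#' * work is dominated by the desk sensor M026 alternating with M027;
#' * eating is hubbed on the dining sensor M014, meal preparation on the
#'   kitchen sensors M015..M019, bed-to-toilet on M004/M005/M007;
#' * self-transitions are rare (0.02) everywhere except the deliberately
#'   repetitive respirating profile, so a sensor repeating itself is
#'   atypical — exactly what sub-activity anomaly injection produces.
#'
#' @return A `routine_model` with exactly 11 profiles over 34 sensors.
#' @export
default_aruba_model <- function() {
  p <- list(
    activity_profile("Sleeping", c("M002", "M003", "M007"),
      trans_matrix(c("M002", "M003", "M007"), list(
        M002 = list(M002 = 0.02, M003 = 0.92, M007 = 0.06),
        M003 = list(M002 = 0.92, M003 = 0.02, M007 = 0.06),
        M007 = list(M002 = 0.49, M003 = 0.49, M007 = 0.02))),
      rate = 0.6, init = c(0.5, 0.5, 0)),
    activity_profile("Bed_to_Toilet", c("M004", "M005", "M007"),
      trans_matrix(c("M004", "M005", "M007"), list(
        M004 = list(M004 = 0.02, M005 = 0.38, M007 = 0.60),
        M005 = list(M004 = 0.28, M005 = 0.02, M007 = 0.70),
        M007 = list(M004 = 0.50, M005 = 0.48, M007 = 0.02))),
      rate = 3, init = c(0.8, 0.1, 0.1)),
    activity_profile("Meal_Preparation",
      c("M015", "M016", "M017", "M018", "M019"),
      trans_matrix(c("M015", "M016", "M017", "M018", "M019"), list(
        M015 = list(M015 = 0.02, M016 = 0.08, M017 = 0.05, M018 = 0.05, M019 = 0.80),
        M016 = list(M015 = 0.35, M016 = 0.02, M019 = 0.63),
        M017 = list(M015 = 0.10, M017 = 0.02, M019 = 0.88),
        M018 = list(M015 = 0.08, M018 = 0.02, M019 = 0.90),
        M019 = list(M015 = 0.48, M016 = 0.15, M017 = 0.13, M018 = 0.22, M019 = 0.02))),
      rate = 3),
    activity_profile("Eating", c("M006", "M008", "M013", "M014"),
      trans_matrix(c("M006", "M008", "M013", "M014"), list(
        M006 = list(M006 = 0.02, M014 = 0.90, M013 = 0.08),
        M008 = list(M008 = 0.02, M014 = 0.90, M013 = 0.08),
        M013 = list(M013 = 0.02, M014 = 0.80, M006 = 0.09, M008 = 0.09),
        M014 = list(M014 = 0.02, M006 = 0.30, M008 = 0.30, M013 = 0.38))),
      rate = 2),
    activity_profile("Work", c("M026", "M027", "M028"),
      trans_matrix(c("M026", "M027", "M028"), list(
        M026 = list(M026 = 0.02, M027 = 0.85, M028 = 0.13),
        M027 = list(M026 = 0.80, M027 = 0.02, M028 = 0.18),
        M028 = list(M026 = 0.75, M027 = 0.23, M028 = 0.02))),
      rate = 2.5, init = c(0.8, 0.2, 0)),
    activity_profile("Relaxing", c("M009", "M010", "M013", "M020"),
      trans_matrix(c("M009", "M010", "M013", "M020"), list(
        M009 = list(M009 = 0.02, M010 = 0.30, M013 = 0.40, M020 = 0.28),
        M010 = list(M009 = 0.70, M010 = 0.02, M013 = 0.28),
        M013 = list(M009 = 0.60, M013 = 0.02, M020 = 0.38),
        M020 = list(M009 = 0.58, M013 = 0.40, M020 = 0.02))),
      rate = 1.2),
    activity_profile("Wash_Dishes", c("M015", "M018", "M019"),
      trans_matrix(c("M015", "M018", "M019"), list(
        M015 = list(M015 = 0.02, M018 = 0.18, M019 = 0.80),
        M018 = list(M015 = 0.10, M018 = 0.02, M019 = 0.88),
        M019 = list(M015 = 0.58, M018 = 0.40, M019 = 0.02))),
      rate = 3),
    activity_profile("Housekeeping", c("M013", "M014", "M018", "M020"),
      trans_matrix(c("M013", "M014", "M018", "M020"), list(
        M013 = list(M013 = 0.02, M014 = 0.40, M018 = 0.28, M020 = 0.30),
        M014 = list(M013 = 0.35, M014 = 0.02, M018 = 0.30, M020 = 0.33),
        M018 = list(M013 = 0.33, M014 = 0.32, M018 = 0.02, M020 = 0.33),
        M020 = list(M013 = 0.40, M014 = 0.30, M018 = 0.28, M020 = 0.02))),
      rate = 2.5),
    activity_profile("Leave_Home", c("M021", "M030", "M031", "D003"),
      trans_matrix(c("M021", "M030", "M031", "D003"), list(
        M021 = list(M021 = 0.02, M030 = 0.88, M031 = 0.10),
        M030 = list(M030 = 0.02, M031 = 0.88, M021 = 0.10),
        M031 = list(M031 = 0.02, D003 = 0.90, M030 = 0.08),
        D003 = list(D003 = 0.10, M031 = 0.90))),
      rate = 4, init = c(1, 0, 0, 0)),
    activity_profile("Enter_Home", c("D003", "M031", "M030", "M021"),
      trans_matrix(c("D003", "M031", "M030", "M021"), list(
        D003 = list(D003 = 0.10, M031 = 0.90),
        M031 = list(M031 = 0.02, M030 = 0.88, M021 = 0.10),
        M030 = list(M030 = 0.02, M021 = 0.88, M031 = 0.10),
        M021 = list(M021 = 0.02, M030 = 0.49, M031 = 0.49))),
      rate = 4, init = c(1, 0, 0, 0)),
    activity_profile("Respirate", c("M025", "M027"),
      trans_matrix(c("M025", "M027"), list(
        M025 = list(M025 = 0.60, M027 = 0.40),
        M027 = list(M025 = 0.90, M027 = 0.10))),
      rate = 1.5, init = c(1, 0))
  )
  sched <- function(activity, start, end) {
    data.frame(activity = activity, start_min = start, end_min = end,
               stringsAsFactors = FALSE)
  }
  schedule <- rbind(
    sched("Sleeping",          0,   178),
    sched("Bed_to_Toilet",   179,   187),
    sched("Sleeping",        188,   390),
    sched("Meal_Preparation", 392,  422),
    sched("Eating",           424,  449),
    sched("Wash_Dishes",      450,  465),
    sched("Work",             468,  588),
    sched("Relaxing",         590,  640),
    sched("Leave_Home",       642,  647),
    sched(NA_character_,      648,  750),   # away
    sched("Enter_Home",       751,  756),
    sched("Meal_Preparation", 758,  788),
    sched("Eating",           790,  815),
    sched("Work",             818,  938),
    sched("Housekeeping",     940,  985),
    sched("Relaxing",         987, 1065),
    sched("Meal_Preparation", 1067, 1102),
    sched("Eating",           1104, 1129),
    sched("Wash_Dishes",      1130, 1145),
    sched("Respirate",        1147, 1167),
    sched("Relaxing",         1169, 1285),
    sched("Sleeping",         1290, 1440)
  )
  routine_model(p, schedule)
}

# Simulate one activity instance on [t0, t1) (POSIXct seconds).
# Returns a data.frame of events or NULL when no event fits.
simulate_instance <- function(profile, t0, t1) {
  dur <- as.numeric(t1) - as.numeric(t0)
  if (dur <= 0) return(NULL)
  rate_sec <- profile$rate / 60
  k <- length(profile$sensors)
  # upper bound on event count, then trim to the span
  nmax <- max(4L, ceiling(dur * rate_sec + 6 * sqrt(dur * rate_sec)) + 4L)
  gaps <- stats::rexp(nmax, rate_sec)
  tt <- as.numeric(t0) + cumsum(gaps)
  tt <- tt[tt < as.numeric(t1)]
  if (length(tt) == 0) return(NULL)
  states <- integer(length(tt))
  states[1] <- sample.int(k, 1, prob = profile$init)
  if (length(tt) > 1) {
    for (i in 2:length(tt)) {
      states[i] <- sample.int(k, 1, prob = profile$transition[states[i - 1], ])
    }
  }
  sens <- profile$sensors[states]
  val <- ifelse(startsWith(sens, "D"), "OPEN", "ON")
  data.frame(time = as.POSIXct(round(tt), tz = "UTC",
                               origin = "1970-01-01"),
             sensor = sens, value = val,
             activity = NA_character_, marker = NA_character_,
             stringsAsFactors = FALSE)
}

#' Generate annotated days of normal routine
#'
#' Simulates `n_days` of the routine model starting at `start_date`. Each
#' day instantiates the schedule with jittered slot boundaries; each slot's
#' activity emits a Markov-chain sensor stream at its event rate. The first
#' and last event of every instance carry `begin`/`end` annotations. Only
#' activations (`ON`/`OPEN`) are emitted: the detection features ignore
#' de-activations, so the simulator does not produce them by default.
#'
#' @param model a `routine_model`.
#' @param n_days number of days (>= 0).
#' @param seed integer seed; the same (model, seed) yields an identical log.
#' @param start_date first day, `Date` or string.
#' @return A fully annotated `event_log`.
#' @export
generate_days <- function(model, n_days, seed = 1L,
                          start_date = "2021-03-01") {
  if (n_days < 0) stop("n_days must be >= 0")
  set.seed(as.integer(seed))
  day0 <- as.POSIXct(paste(as.Date(start_date), "00:00:00"), tz = "UTC")
  out <- list()
  for (d in seq_len(n_days)) {
    base <- day0 + (d - 1) * 86400
    sch <- model$schedule
    jit <- stats::rnorm(nrow(sch), 0, model$jitter_sd)
    start <- sch$start_min + jit
    end <- sch$end_min + jit
    # keep slots inside the day and non-overlapping after jitter
    start <- pmax(0, pmin(start, 1439))
    end <- pmax(start + 0.5, pmin(end, 1440))
    if (nrow(sch) > 1) {
      for (i in 2:nrow(sch)) start[i] <- max(start[i], end[i - 1])
      end <- pmax(end, start + 0.5)
    }
    for (i in seq_len(nrow(sch))) {
      act <- sch$activity[i]
      if (is.na(act)) next
      ev <- simulate_instance(model$profiles[[act]],
                              base + start[i] * 60, base + end[i] * 60)
      if (is.null(ev) || nrow(ev) < 2) next   # an instance needs begin + end
      ev$activity[c(1, nrow(ev))] <- act
      ev$marker[1] <- "begin"
      ev$marker[nrow(ev)] <- "end"
      out[[length(out) + 1]] <- ev
    }
  }
  if (length(out) == 0) return(event_log())
  df <- do.call(rbind, out)
  df <- df[order(df$time, method = "radix"), , drop = FALSE]
  validate_event_log(df)
  as_event_log(df)
}
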