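#' Segment an event log into fixed-length windows
#'
#' Tiles the log's time span with consecutive (tumbling) windows of
#' `window_minutes` and assigns every activation (`ON`/`OPEN` event) to
#' exactly one window. De-activations (`OFF`/`CLOSE`) are ignored: the
#' representations only consider sensor activations. When annotations exist,
#' each window takes the majority activity label by event count, with ties
#' going to the activity that appears earlier in the window.
#'
#' @param log a time-sorted `event_log`.
#' @param window_minutes window length in minutes (> 0), default 1.
#' @param registry `sensor_registry` defining token indices.
#' @return A data frame of class `window_chunks`, one row per window tiling
#'   the span: `start`, `end` (POSIXct), `tokens` (list column of 1-based
#'   registry indices in activation order), `n_tokens`, `label`.
#' @export
segment_windows <- function(log, window_minutes = 1,
                            registry = default_registry()) {
  if (window_minutes <= 0) stop("window_minutes must be > 0")
  empty <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      n_tokens = integer(), label = character(),
                      stringsAsFactors = FALSE)
  empty$tokens <- list()
  if (nrow(log) == 0) {
    class(empty) <- c("window_chunks", "data.frame")
    return(empty)
  }
  wsec <- window_minutes * 60
  act <- log$value %in% c("ON", "OPEN")
  t0 <- floor(min(as.numeric(log$time)) / wsec) * wsec
  nwin <- ceiling((max(as.numeric(log$time)) + 1 - t0) / wsec)
  wid <- pmin(nwin, floor((as.numeric(log$time) - t0) / wsec) + 1)
  tok_all <- sensor_index(registry, log$sensor)
  labels_all <- event_activities(log)
  tokens <- rep(list(integer()), nwin)
  tok_by_win <- split(tok_all[act], factor(wid[act], levels = seq_len(nwin)))
  tokens[seq_len(nwin)] <- tok_by_win
  lab <- rep(NA_character_, nwin)
  for (w in unique(wid)) {
    l <- labels_all[wid == w]
    l <- l[!is.na(l)]
    if (length(l) == 0) next
    counts <- table(factor(l, levels = unique(l)))  # unique() keeps first-seen order
    lab[w] <- names(counts)[which.max(counts)]      # ties -> earlier activity
  }
  out <- data.frame(
    start = as.POSIXct(t0 + (seq_len(nwin) - 1) * wsec, tz = "UTC",
                       origin = "1970-01-01"),
    end = as.POSIXct(t0 + seq_len(nwin) * wsec, tz = "UTC",
                     origin = "1970-01-01"),
    n_tokens = lengths(tokens), label = lab, stringsAsFactors = FALSE)
  out$tokens <- tokens
  class(out) <- c("window_chunks", "data.frame")
  out
}

#' Bag-of-sensors (BOS) vector of a window
#'
#' A binary presence vector of length N (the registry size): position j is 1
#' iff sensor j was activated at least once in the window. Activation order
#' and frequency are discarded by construction.
#'
#' @param tokens integer vector of registry indices (a `tokens` entry of
#'   [segment_windows()]) or a single `window_chunks` row.
#' @param registry the `sensor_registry`.
#' @return integer vector of 0/1 of length `length(registry)`.
#' @export
bos_vector <- function(tokens, registry = default_registry()) {
  tokens <- chunk_tokens(tokens)
  n <- length(registry)
  if (length(tokens) && (min(tokens) < 1 || max(tokens) > n)) {
    stop("token index outside registry (1..", n, ")")
  }
  v <- integer(n)
  v[tokens] <- 1L
  v
}

#' Raw-sensor-measurement (RSM) sequence of a window
#'
#' The ordered, repeat-preserving activation sequence, plus its one-hot
#' matrix view: row i is the one-hot encoding of the i-th activation, so a
#' window with k activations over an N-sensor registry yields a k x N
#' matrix. Unlike BOS, frequency and order are preserved.
#'
#' @inheritParams bos_vector
#' @return A list of class `rsm_sequence`: `tokens` (integer vector),
#'   `onehot` (k x N matrix), `sensors` (canonical ids).
#' @export
rsm_sequence <- function(tokens, registry = default_registry()) {
  tokens <- chunk_tokens(tokens)
  n <- length(registry)
  if (length(tokens) && (min(tokens) < 1 || max(tokens) > n)) {
    stop("token index outside registry (1..", n, ")")
  }
  k <- length(tokens)
  onehot <- matrix(0, nrow = k, ncol = n)
  if (k) onehot[cbind(seq_len(k), tokens)] <- 1
  structure(list(tokens = tokens, onehot = onehot,
                 sensors = unclass(registry)[tokens]),
            class = "rsm_sequence")
}

chunk_tokens <- function(tokens) {
  if (inherits(tokens, "window_chunks") || is.data.frame(tokens)) {
    stopifnot(nrow(tokens) == 1)
    tokens <- tokens$tokens[[1]]
  }
  as.integer(tokens)
}

#' BOS matrix for a whole window table
#'
#' @param chunks a `window_chunks` table.
#' @param registry the `sensor_registry`.
#' @return matrix of shape `nrow(chunks)` x N with 0/1 entries.
#' @export
bos_matrix <- function(chunks, registry = default_registry()) {
  t(vapply(chunks$tokens, bos_vector, integer(length(registry)),
           registry = registry))
}

#' Render a BOS vector as the conventional bit-string
#'
#' @param v a 0/1 vector.
#' @return single string, e.g. `"00111010..."`.
#' @export
bos_bitstring <- function(v) paste(as.integer(v), collapse = "")
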