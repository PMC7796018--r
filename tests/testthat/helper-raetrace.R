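# Shared fixtures and oracles for the suite. Everything is built in code.

REG <- default_registry()

# A tiny two-activity routine model for fast generator-dependent tests.
tiny_model <- function() {
  profiles <- list(
    activity_profile("Sleeping", c("M002", "M003"),
                     matrix(c(0.1, 0.9, 0.9, 0.1), 2, byrow = TRUE),
                     rate = 2),
    activity_profile("Work", c("M026", "M027"),
                     matrix(c(0.1, 0.9, 0.9, 0.1), 2, byrow = TRUE),
                     rate = 3)
  )
  schedule <- data.frame(
    activity = c("Sleeping", "Work", NA, "Sleeping"),
    start_min = c(0, 480, 720, 1320),
    end_min = c(420, 700, 1320, 1440),
    stringsAsFactors = FALSE)
  routine_model(profiles, schedule, jitter_sd = 1)
}

# Central-difference gradient of f at params over the named components.
numerical_gradient <- function(f, params, pnames, eps = 1e-6) {
  out <- list()
  for (nm in pnames) {
    g <- params[[nm]] * 0
    for (i in seq_along(params[[nm]])) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      g[i] <- (f(up) - f(dn)) / (2 * eps)
    }
    out[[nm]] <- g
  }
  out
}

max_rel_err <- function(ga, gn, pnames) {
  max(vapply(pnames, function(nm) {
    max(abs(ga[[nm]] - gn[[nm]])) / max(1e-8, max(abs(gn[[nm]])))
  }, 0))
}

# Brute-force replay of greedy construction used as the independent oracle:
# at every level evaluate each adjacent pair with encode/decode directly.
greedy_oracle_structure <- function(tokens, params, registry = REG) {
  V <- t(rsm_sequence(tokens, registry)$onehot)
  k <- ncol(V)
  ids <- seq_len(k)
  s <- matrix(0L, max(k - 1, 0), 2)
  for (j in seq_len(k - 1)) {
    m <- ncol(V)
    errs <- vapply(seq_len(m - 1), function(i) {
      p <- encode_pair(V[, i], V[, i + 1], params)
      r <- decode_pair(p, params)
      reconstruction_error(c(V[, i], V[, i + 1]), c(r$c1, r$c2))
    }, 0)
    i <- which.min(errs)
    s[j, ] <- c(ids[i], ids[i + 1])
    V[, i] <- encode_pair(V[, i], V[, i + 1], params)
    V <- V[, -(i + 1), drop = FALSE]
    ids[i] <- k + j
    ids <- ids[-(i + 1)]
  }
  s
}

n_inserted <- function(records) {
  sum(vapply(records, function(r) length(r$event_idx), 0L))
}

# TRUE iff the rows of `sub` appear in order as a subsequence of `full`
# (field-wise comparison on time/sensor/value).
is_subsequence_log <- function(sub, full) {
  key <- function(l) paste(format(l$time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                           l$sensor, l$value)
  ks <- key(sub); kf <- key(full)
  j <- 1
  for (i in seq_along(ks)) {
    while (j <= length(kf) && kf[j] != ks[i]) j <- j + 1
    if (j > length(kf)) return(FALSE)
    j <- j + 1
  }
  TRUE
}
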