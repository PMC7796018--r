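#' Sensor registry
#'
#' A registry fixes the ordered set of sensors a deployment exposes, so that
#' bag-of-sensors vectors and one-hot rows have a stable length and column
#' order across files. Registries are declared up front (not inferred from
#' data): a log that happens to miss a quiet sensor must still produce
#' vectors of the full length.
#'
#' Sensor ids follow the CASAS convention: motion sensors `M001`, `M002`, ...
#' and door sensors `D001`, ... Short forms such as `"M3"` are normalised to
#' `"M003"`. User-facing positions are 1-based: sensor `M7` occupies position
#' 7 of a default registry.
#'
#' @param sensors character vector of sensor ids (short or canonical form).
#' @return An object of class `sensor_registry`: the canonical id vector with
#'   a name-to-index lookup attached.
#' @examples
#' reg <- default_registry()
#' length(reg)                      # 34
#' sensor_index(reg, c("M7", "M3"))
#' @export
sensor_registry <- function(sensors) {
  ids <- canonical_sensor(sensors)
  if (anyDuplicated(ids)) {
    stop("duplicate sensor ids in registry: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(ids))) stop("empty sensor id in registry")
  structure(ids, class = "sensor_registry")
}

#' Default Aruba-style registry: 31 motion + 3 door sensors
#'
#' Mirrors the single-resident testbed layout used throughout the package:
#' motion sensors M001..M031 at positions 1..31 and door sensors D001..D003
#' at positions 32..34, for a total of N = 34 sensors.
#'
#' @return A `sensor_registry` of length 34.
#' @export
default_registry <- function() {
  sensor_registry(c(sprintf("M%03d", 1:31), sprintf("D%03d", 1:3)))
}

#' Normalise sensor ids to canonical zero-padded form
#'
#' @param ids character vector, e.g. `c("M3", "M026", "D1")`.
#' @return character vector of canonical ids, e.g. `c("M003", "M026", "D001")`.
#' @export
canonical_sensor <- function(ids) {
  ids <- as.character(ids)
  m <- regmatches(ids, regexec("^([A-Za-z]+)0*([0-9]+)$", ids))
  bad <- lengths(m) != 3L
  if (any(bad)) stop("unparseable sensor id(s): ", paste(ids[bad], collapse = ", "))
  vapply(m, function(p) sprintf("%s%03d", toupper(p[2]), as.integer(p[3])), "")
}

#' Map sensor ids to registry indices
#'
#' @param registry a `sensor_registry`.
#' @param ids character vector of sensor ids (any accepted form).
#' @return integer vector of 1-based registry positions.
#' @export
sensor_index <- function(registry, ids) {
  idx <- match(canonical_sensor(ids), unclass(registry))
  if (anyNA(idx)) {
    stop("sensor id(s) not in registry: ",
         paste(unique(ids[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' @export
print.sensor_registry <- function(x, ...) {
  cat("<sensor_registry> ", length(x), " sensors: ",
      paste(utils::head(unclass(x), 5), collapse = ", "),
      if (length(x) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}
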