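# Deterministic classifiers from numeric measurements onto the categorical
# scales. Class boundaries live in the packaged vocabulary tables (num_lo /
# num_hi columns), not in code, so a chart revision is a data change.

#' Classify an area into a spatial scale class
#'
#' The five classes partition the positive areas: Point (below 1 m2),
#' Plot (1 m2 up to 0.01 km2), Region (up to 10000 km2), Continent (up to
#' 100000000 km2) and Global (larger). Lower bounds are inclusive, so a
#' boundary value belongs to the upper class.
#'
#' @param area positive finite area.
#' @param unit \code{"m2"} or \code{"km2"} (converted exactly by 1e6).
#' @param vocab vocabulary carrying the class boundary table.
#' @return the class label, one of Point, Plot, Region, Continent, Global.
#' @export
#' @examples
#' classify_spatial_scale(0.5)            # "Point"
#' classify_spatial_scale(5000, "km2")    # "Region"
classify_spatial_scale <- function(area, unit = c("m2", "km2"),
                                   vocab = default_vocabulary()) {
  unit <- match.arg(unit)
  if (!is.numeric(area) || length(area) != 1L || !is.finite(area) || area <= 0)
    stop("area must be a single positive finite number")
  m2 <- if (unit == "km2") area * 1e6 else area
  for (t in terms_at(vocab, "space/scale"))
    if (m2 >= t$num_lo && (is.na(t$num_hi) || m2 < t$num_hi)) return(t$label)
  stop("spatial scale classes do not cover area ", m2, " m2")  # unreachable
}

#' Classify a time interval into a time-unit class
#'
#' Floor rule: the largest unit whose nominal span is not longer than the
#' interval. Nominal spans come from the packaged time-unit table (Month =
#' 30 days, Year = 365 days, Decade = 10 such years).
#'
#' @param seconds positive interval length in seconds.
#' @inheritParams classify_spatial_scale
#' @return the unit class label (Second, Minute, Hour, Day, ...).
#' @export
#' @examples
#' classify_time_unit(3600)   # "Hour"
#' classify_time_unit(59)     # "Second"
classify_time_unit <- function(seconds, vocab = default_vocabulary()) {
  if (!is.numeric(seconds) || length(seconds) != 1L || !is.finite(seconds) ||
      seconds <= 0)
    stop("interval must be a single positive finite number of seconds")
  units <- terms_at(vocab, "time/unit")
  spans <- vapply(units, `[[`, 0, "num_lo")
  fit <- which(spans <= seconds)
  if (!length(fit)) return(units[[1]]$label)  # sub-second: finest class
  units[[max(fit)]]$label
}

#' Geological context of a numeric age
#'
#' Returns the chain of chart units covering an age in Ma before present,
#' one term per rank from eon downwards (finer ranks are omitted where the
#' chart does not subdivide, e.g. the Hadean). An age exactly on a unit
#' boundary belongs to the younger unit. Units' numeric spans come from the
#' packaged chart table; informal rank terms without a numeric span (the
#' Precambrian grouping) never match.
#'
#' @param age_ma age in millions of years before present (>= 0).
#' @inheritParams classify_spatial_scale
#' @return named list of \code{eco_term}s, names among eon, era, period,
#'   epoch, age.
#' @export
#' @examples
#' names(geological_context(0.001))   # eon era period epoch
geological_context <- function(age_ma, vocab = default_vocabulary()) {
  if (!is.numeric(age_ma) || length(age_ma) != 1L || !is.finite(age_ma) ||
      age_ma < 0)
    stop("age must be a single finite number of Ma >= 0")
  ranks <- c("eon", "era", "period", "epoch", "age")
  span_max <- max(vapply(terms_at(vocab, "time/geological/eon"),
                         function(t) if (is.na(t$num_hi)) -Inf else t$num_hi, 0))
  if (age_ma > span_max)
    stop("age ", age_ma, " Ma is beyond the packaged chart span (",
         span_max, " Ma)")
  out <- list()
  parent <- NULL
  for (rk in ranks) {
    cands <- terms_at(vocab, paste0("time/geological/", rk))
    hit <- NULL
    for (t in cands) {
      if (is.na(t$num_hi)) next
      if (!is.null(parent) && !identical(t$parent_id, parent$id)) next
      # younger-unit boundary rule: num_lo < age <= num_hi, youngest reaches 0
      if ((age_ma > t$num_lo || (t$num_lo == 0 && age_ma >= 0)) &&
          age_ma <= t$num_hi) { hit <- t; break }
    }
    if (is.null(hit)) break
    out[[rk]] <- hit
    parent <- hit
  }
  out
}

#' Bounding box containment
#'
#' Inclusive edges; boxes with \code{west > east} wrap across the
#' antimeridian.
#' @param box named list/vector with \code{west}, \code{south}, \code{east},
#'   \code{north} in decimal degrees.
#' @param latitude,longitude point coordinates in WGS84 decimal degrees.
#' @return logical.
#' @export
#' @examples
#' bbox_contains(list(west = 170, south = -10, east = -170, north = 10), 0, 179)
bbox_contains <- function(box, latitude, longitude) {
  box <- as.list(box)
  vals <- c(box$west, box$south, box$east, box$north, latitude, longitude)
  if (length(vals) != 6 || !all(is.finite(vals)))
    stop("box and coordinates must be finite numbers")
  if (abs(latitude) > 90 || abs(longitude) > 180 ||
      abs(box$south) > 90 || abs(box$north) > 90 ||
      abs(box$west) > 180 || abs(box$east) > 180)
    stop("coordinates out of range")
  lat_ok <- latitude >= box$south && latitude <= box$north
  lon_ok <- if (box$west <= box$east) longitude >= box$west && longitude <= box$east
            else longitude >= box$west || longitude <= box$east
  lat_ok && lon_ok
}
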