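#' Climb rate from an altitude series
#'
#' Smooths the altitude over a centered window of approximately
#' `smooth_seconds` seconds, then takes the first difference divided by the
#' timestep. Values are reported at the midpoints of consecutive samples.
#'
#' @param time Timestamps (s), approximately uniform.
#' @param altitude Altitude series (m).
#' @param smooth_seconds Smoothing span in seconds (default 2 s).
#' @return A data frame `time`, `v_z` (m/s); empty when the series is shorter
#'   than the smoothing window.
#' @export
climb_rate <- function(time, altitude, smooth_seconds = 2) {
  stopifnot(length(time) == length(altitude))
  n <- length(time)
  if (n < 2) return(data.frame(time = numeric(), v_z = numeric()))
  dt <- median(diff(time))
  # centered window spanning +/- smooth_seconds/2 around each sample
  w <- 2L * as.integer(floor(smooth_seconds / (2 * dt) + 1e-9)) + 1L
  if (w > n) return(data.frame(time = numeric(), v_z = numeric()))
  s <- smooth_signal(altitude, w)
  data.frame(time = (time[-1] + time[-n]) / 2,
             v_z = diff(s) / diff(time))
}

#' Airspeed from the wind triangle
#'
#' Magnitude of the horizontal groundspeed vector minus the wind vector; the
#' vertical component is ignored. Invariant under a common rotation of both
#' vectors.
#'
#' @param groundspeed Length-2 vector or 2-column matrix (m/s).
#' @param wind Length-2 vector or 2-column matrix (m/s, to-direction).
#' @return Airspeed(s), m/s (non-negative).
#' @export
airspeed <- function(groundspeed, wind) {
  g <- rbind_vec2(groundspeed)
  w <- rbind_vec2(wind)
  if (nrow(w) == 1 && nrow(g) > 1) w <- w[rep(1, nrow(g)), , drop = FALSE]
  if (nrow(g) == 1 && nrow(w) > 1) g <- g[rep(1, nrow(w)), , drop = FALSE]
  sqrt((g[, 1] - w[, 1])^2 + (g[, 2] - w[, 2])^2)
}

rbind_vec2 <- function(v) {
  if (is.matrix(v) || is.data.frame(v)) {
    v <- as.matrix(v)
    stopifnot(ncol(v) == 2)
    return(v)
  }
  stopifnot(length(v) == 2)
  matrix(v, nrow = 1)
}

#' Build the flight-state timeline
#'
#' Converts the barometric pressure stream to altitude
#' ([barometric_altitude()]), differentiates the 2-s-smoothed altitude to a
#' climb rate ([climb_rate()]), computes the wind-triangle airspeed at each
#' track fix, and flags level flight (strictly `lower < v_z < upper`). Climb
#' rate is interpolated onto the track timeline.
#'
#' @param track Data frame with `time`, `groundspeed_x`, `groundspeed_y`.
#' @param pressure Data frame with `time`, `pa` (Pa).
#' @param wind Either a length-2 vector, or a data frame with `time`, `wx`,
#'   `wy` (nearest-in-time lookup).
#' @param reference_pressure Sea-level reference pressure (Pa).
#' @param smooth_seconds Altitude smoothing span for the climb rate.
#' @param level_bounds Open-interval climb-rate bounds (m/s) defining level
#'   flight.
#' @return A data frame of class `flight_state`: `time`, `altitude`, `v_z`,
#'   `airspeed`, `groundspeed_x`, `groundspeed_y`, `level`.
#' @export
flight_state <- function(track, pressure, wind,
                         reference_pressure = 101325,
                         smooth_seconds = 2,
                         level_bounds = c(-0.2, 0.2)) {
  stopifnot(all(c("time", "groundspeed_x", "groundspeed_y") %in% names(track)),
            all(c("time", "pa") %in% names(pressure)))
  alt <- barometric_altitude(pressure$pa, reference_pressure)
  cr <- climb_rate(pressure$time, alt, smooth_seconds)
  if (!nrow(cr)) stop("pressure series too short to derive a climb rate")
  vz <- approx(cr$time, cr$v_z, xout = track$time, rule = 2)$y
  altitude <- approx(pressure$time, alt, xout = track$time, rule = 2)$y
  if (is.data.frame(wind)) {
    wi <- vapply(track$time, function(tt) which.min(abs(wind$time - tt)), integer(1))
    wv <- cbind(wind$wx[wi], wind$wy[wi])
  } else {
    wv <- rbind_vec2(wind)
  }
  va <- airspeed(cbind(track$groundspeed_x, track$groundspeed_y), wv)
  out <- data.frame(time = track$time, altitude = altitude, v_z = vz,
                    airspeed = va,
                    groundspeed_x = track$groundspeed_x,
                    groundspeed_y = track$groundspeed_y,
                    level = vz > level_bounds[1] & vz < level_bounds[2])
  class(out) <- c("flight_state", "data.frame")
  attr(out, "level_bounds") <- level_bounds
  out
}

# Time-weighted mean of a sampled series over [a, b], integrating the linear
# interpolant (trapezoid on the union of sample times within the span and the
# span endpoints).
span_mean <- function(time, x, a, b) {
  if (b <= a) return(NA_real_)
  tt <- sort(unique(c(a, b, time[time > a & time < b])))
  xx <- approx(time, x, xout = tt, rule = 2)$y
  sum((xx[-1] + xx[-length(xx)]) / 2 * diff(tt)) / (b - a)
}

#' Attach flight-state averages to kinematic intervals
#'
#' For each interval span the altitude, climb rate and airspeed are averaged
#' by time-weighted mean, and the fraction of the span spent in level
#' flapping flight is computed (the state's `level` flag, treated as
#' piecewise-constant between state samples; the interval itself spans
#' detected wingbeat cycles, so flapping is given).
#'
#' @param intervals Interval table from [average_intervals()].
#' @param state A [flight_state()] timeline.
#' @return `intervals` with columns `altitude`, `v_z`, `airspeed`,
#'   `fraction_level_flapping` added.
#' @export
attach_flight_state <- function(intervals, state) {
  if (!nrow(intervals)) {
    intervals[c("altitude", "v_z", "airspeed", "fraction_level_flapping")] <-
      list(numeric(), numeric(), numeric(), numeric())
    return(intervals)
  }
  lev <- as.numeric(state$level)
  intervals$altitude <- mapply(span_mean, a = intervals$start, b = intervals$end,
                               MoreArgs = list(time = state$time, x = state$altitude))
  intervals$v_z <- mapply(span_mean, a = intervals$start, b = intervals$end,
                          MoreArgs = list(time = state$time, x = state$v_z))
  intervals$airspeed <- mapply(span_mean, a = intervals$start, b = intervals$end,
                               MoreArgs = list(time = state$time, x = state$airspeed))
  intervals$fraction_level_flapping <- mapply(function(a, b) {
    step_fraction(state$time, lev, a, b)
  }, a = intervals$start, b = intervals$end)
  intervals
}

# Fraction of [a, b] where a piecewise-constant (left-continuous) 0/1 series
# is 1.
step_fraction <- function(time, ind, a, b) {
  if (b <= a) return(NA_real_)
  tt <- sort(unique(c(a, b, time[time > a & time < b])))
  i <- pmax(findInterval(tt[-length(tt)], time), 1L)
  sum(ind[i] * diff(tt)) / (b - a)
}

#' Select level flapping flight
#'
#' Retains rows satisfying the strict open-interval climb-rate test
#' `lower < v_z < upper` (default -0.2 and 0.2 m/s). When the input carries a
#' `fraction_level_flapping` column (interval data), at least `min_fraction`
#' (default 80%) of the span must additionally be level flapping flight.
#'
#' @param x Data frame with a `v_z` column (samples or intervals).
#' @param level_bounds Open-interval bounds (m/s).
#' @param min_fraction Minimum level-flapping fraction for interval data
#'   (inclusive).
#' @return The retained subset.
#' @export
select_level_flight <- function(x, level_bounds = c(-0.2, 0.2),
                                min_fraction = 0.8) {
  stopifnot("v_z" %in% names(x))
  keep <- x$v_z > level_bounds[1] & x$v_z < level_bounds[2]
  if ("fraction_level_flapping" %in% names(x)) {
    keep <- keep & x$fraction_level_flapping >= min_fraction
  }
  out <- x[keep & !is.na(keep), , drop = FALSE]
  stopifnot(all(out$v_z > level_bounds[1] & out$v_z < level_bounds[2]))
  rownames(out) <- NULL
  out
}

#' Restrict intervals to the central airspeed window
#'
#' Retains rows whose airspeed lies within the overall mean plus/minus one
#' sample standard deviation (inclusive), computed over the input set. Used
#' to minimize airspeed variation in climb-rate analyses.
#'
#' @param x Data frame with an airspeed column.
#' @param col Airspeed column name.
#' @return The retained subset, with attributes `mean` and `sd`.
#' @export
airspeed_window_filter <- function(x, col = "airspeed") {
  stopifnot(col %in% names(x))
  v <- x[[col]]
  if (sum(!is.na(v)) < 2) stop("need at least 2 airspeed values to form the mean +/- sd window")
  m <- mean(v, na.rm = TRUE)
  s <- sd(v, na.rm = TRUE)
  keep <- !is.na(v) & v >= m - s & v <= m + s
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mean") <- m
  attr(out, "sd") <- s
  out
}
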