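# Wing kinematics engine.
#
# The wing elevation angle is a pair of half-cosines on the cycle phase u in
# [0, 1): the downstroke occupies u in [0, d) and runs from +A/2 down to
# -A/2, the upstroke returns over u in [d, 1). The phase advances at the
# instantaneous wingbeat frequency and pauses during glide bouts. A glide
# begins once the stroke in progress completes (the next integer phase),
# where the wing angular velocity is zero, so the heave signal stays smooth
# across glide boundaries; flapping resumes at the configured bout end. All
# phase bookkeeping is done on a fine internal grid (trapezoidal integration
# of the frequency profile), which is exact for piecewise-linear frequency
# profiles.

wing_phase_grid <- function(config) {
  dur <- config$duration
  fmax <- max(profile_values(config$wingbeat_frequency,
                             seq(0, dur, length.out = 401), dur))
  rate <- max(2000, 100 * fmax)
  tg <- seq(0, dur, by = 1 / rate)
  if (tg[length(tg)] < dur) tg <- c(tg, dur)
  tg <- sort(unique(c(tg, unlist(config$glide_bouts))))
  f <- profile_values(config$wingbeat_frequency, tg, dur)
  # free-running phase (no glides)
  phi_free <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * diff(tg)))

  bouts <- config$glide_bouts
  if (length(bouts)) {
    bouts <- bouts[order(vapply(bouts, `[`, numeric(1), 1))]
    st <- vapply(bouts, `[`, numeric(1), 1)
    en <- vapply(bouts, `[`, numeric(1), 2)
    if (any(st[-1] < en[-length(en)])) stop("glide bouts must not overlap")
  }

  phi <- phi_free
  pauses <- matrix(numeric(0), ncol = 2) # effective glide [start, end) times
  for (b in bouts) {
    # phase at the nominal bout start, under pauses applied so far
    ia <- which(tg >= b[1])[1]
    phi_a <- approx(tg, phi, xout = b[1])$y
    k <- ceiling(phi_a - 1e-9)
    # time at which the running phase reaches k (stroke completes)
    win <- tg >= b[1] & tg <= b[2]
    if (!any(win) || max(phi[win]) < k) next  # bout too short: no pause
    s <- if (phi_a >= k - 1e-12) b[1] else {
      iw <- which(win & phi >= k)[1]
      tg[iw - 1] + (k - phi[iw - 1]) / (phi[iw] - phi[iw - 1]) *
        (tg[iw] - tg[iw - 1])
    }
    # subtract the phase that would have accrued during [s, b[2])
    lost <- approx(tg, phi, xout = b[2])$y - k
    phi <- ifelse(tg <= s, phi,
                  ifelse(tg < b[2], k, phi - lost))
    pauses <- rbind(pauses, c(s, b[2]))
  }
  list(time = tg, phi = phi, pauses = pauses)
}

in_glide <- function(t, bouts) {
  g <- rep(FALSE, length(t))
  if (is.matrix(bouts)) {
    if (nrow(bouts)) for (j in seq_len(nrow(bouts))) {
      g <- g | (t >= bouts[j, 1] & t < bouts[j, 2])
    }
  } else {
    for (b in bouts) g <- g | (t >= b[1] & t < b[2])
  }
  g
}

elevation_from_u <- function(u, A, d) {
  ifelse(u < d,
         (A / 2) * cos(pi * u / d),
         -(A / 2) * cos(pi * (u - d) / (1 - d)))
}

# dtheta/du in degrees per unit phase
elevation_du <- function(u, A, d) {
  ifelse(u < d,
         -(A / 2) * (pi / d) * sin(pi * u / d),
         (A / 2) * (pi / (1 - d)) * sin(pi * (u - d) / (1 - d)))
}

#' Simulate the wing elevation waveform
#'
#' Generates the ground-truth wing motion for a [sim_config()]: a periodic
#' elevation angle at the configured instantaneous wingbeat frequency, with a
#' downstroke/upstroke duration split of `downstroke_fraction` to
#' `1 - downstroke_fraction`, constant elevation during glide bouts, and the
#' exact cycle boundaries as ground truth.
#'
#' @param config A [sim_config()] object.
#' @param rate Sampling rate (Hz) of the returned sample frame; defaults to
#'   the accelerometer rate.
#' @return An object of class `wing_motion`: a list with `samples` (a data
#'   frame of `time`, `elevation` in degrees and `phase_label`
#'   "downstroke"/"upstroke"/"glide"), `cycles` (ground-truth cycle table
#'   with start/end times, period, frequency and true peak-to-peak wing
#'   amplitude), and evaluator functions `elevation(t)` (degrees),
#'   `omega(t)` (wing angular velocity, rad/s), `phase(t)` (cycle phase) and
#'   `flapping(t)`.
#' @export
simulate_wing_motion <- function(config, rate = config$accel_rate) {
  stopifnot(inherits(config, "sim_config"))
  grid <- wing_phase_grid(config)
  dur <- config$duration
  d <- config$downstroke_fraction

  phase_at <- function(t) approx(grid$time, grid$phi, xout = t, rule = 2)$y
  flap_at <- function(t) !in_glide(t, grid$pauses)
  amp_at <- function(t) profile_values(config$wing_amplitude, t, dur)
  freq_at <- function(t) profile_values(config$wingbeat_frequency, t, dur)

  elev_at <- function(t) {
    u <- phase_at(t) %% 1
    elevation_from_u(u, amp_at(t), d)
  }
  # wing angular velocity in rad/s; zero while gliding
  omega_at <- function(t) {
    u <- phase_at(t) %% 1
    dthdu <- elevation_du(u, amp_at(t), d) * pi / 180
    dthdu * freq_at(t) * as.numeric(flap_at(t))
  }

  # Cycle boundaries: the first time the phase reaches each integer, plus the
  # resume time of each glide pause. Segments over which the phase advances
  # by ~1 are true cycles; zero-advance segments are glides and are dropped,
  # so the cycle table tiles the flapping bouts exactly.
  n_cross <- floor(grid$phi[length(grid$phi)] + 1e-9)
  if (n_cross >= 1) {
    cross <- vapply(0:n_cross, function(k) {
      i <- which(grid$phi >= k - 1e-12)[1]
      if (i == 1 || grid$phi[i] - grid$phi[i - 1] == 0) return(grid$time[i])
      grid$time[i - 1] + (k - grid$phi[i - 1]) /
        (grid$phi[i] - grid$phi[i - 1]) * (grid$time[i] - grid$time[i - 1])
    }, numeric(1))
    bounds <- sort(unique(c(cross, grid$pauses[, 2][grid$pauses[, 2] < dur])))
    st <- bounds[-length(bounds)]
    en <- bounds[-1]
    adv <- phase_at(en) - phase_at(st)
    keep <- adv > 0.5
    st <- st[keep]; en <- en[keep]
    mid <- (st + en) / 2
    cycles <- data.frame(
      cycle = seq_along(st),
      start_time = st,
      end_time = en,
      period = en - st,
      frequency = 1 / (en - st),
      wing_amplitude = amp_at(mid)
    )
  } else {
    cycles <- data.frame(cycle = integer(), start_time = numeric(),
                         end_time = numeric(), period = numeric(),
                         frequency = numeric(), wing_amplitude = numeric())
  }

  ts <- seq(0, dur, by = 1 / rate)
  u <- phase_at(ts) %% 1
  lab <- ifelse(flap_at(ts), ifelse(u < d, "downstroke", "upstroke"), "glide")
  samples <- data.frame(time = ts, elevation = elev_at(ts), phase_label = lab)

  structure(list(samples = samples, cycles = cycles,
                 elevation = elev_at, omega = omega_at,
                 phase = phase_at, flapping = flap_at,
                 config = config),
            class = "wing_motion")
}

#' @export
print.wing_motion <- function(x, ...) {
  cat(sprintf("<wing_motion> %g s, %d ground-truth cycles, mean f = %.3g Hz\n",
              x$config$duration, nrow(x$cycles),
              if (nrow(x$cycles)) mean(x$cycles$frequency) else NA))
  invisible(x)
}

sample_times <- function(duration, nominal_rate, offset = 0, jitter = 0) {
  rate <- nominal_rate + offset
  if (rate <= 0) stop("actual sampling rate must be positive")
  t <- seq(0, duration, by = 1 / rate)
  if (jitter > 0) {
    t <- t + runif(length(t), -jitter, jitter) / rate
    t <- pmin(pmax(t, 0), duration)
    t <- sort(t)
  }
  t
}

new_trace <- function(time, x, y, z, nominal_rate, units, axes) {
  tr <- data.frame(time = time, x = x, y = y, z = z)
  attr(tr, "nominal_rate") <- nominal_rate
  attr(tr, "units") <- units
  attr(tr, "axes") <- axes
  class(tr) <- c("triax_trace", "data.frame")
  tr
}

#' Simulate the body-mounted accelerometer
#'
#' Generates a tri-axial acceleration trace (g) from a wing motion. The heave
#' (z, dorsoventral) channel carries 1 g of static gravity plus a dynamic
#' component proportional to the downward wing angular velocity — a
#' linearized quasi-steady lift response, whose maximum falls exactly at the
#' downstroke midpoint where the wing traverses the body at top speed — plus
#' i.i.d. Gaussian noise. Surge (x) and sway (y) carry noise only.
#'
#' @param motion A `wing_motion` from [simulate_wing_motion()].
#' @param config The same [sim_config()].
#' @return A `triax_trace` data frame (`time`, `x`, `y`, `z`) sampled at the
#'   accelerometer rate (plus any configured rate offset and timestamp
#'   jitter).
#' @export
simulate_accelerometer <- function(motion, config) {
  stopifnot(inherits(motion, "wing_motion"), inherits(config, "sim_config"))
  t <- sample_times(config$duration, config$accel_rate,
                    config$rate_offset[["accel"]], config$timestamp_jitter)
  n <- length(t)
  sdn <- config$noise_sd[["accel"]]
  heave <- 1 - config$heave_gain * motion$omega(t) + rnorm(n, 0, sdn)
  new_trace(t, rnorm(n, 0, sdn), rnorm(n, 0, sdn), heave,
            config$accel_rate, "g", c(x = "surge", y = "sway", z = "heave"))
}

#' Simulate the magnetometer with a wing-mounted magnet
#'
#' The sensed field is the constant geomagnetic vector plus a dipole term of
#' magnitude `magnet_moment / r(t)^3` along a fixed direction, where the
#' magnet-sensor distance `r(t)` maps linearly from the wing elevation over
#' its anatomical range: a fully raised wing (+90 deg) gives the minimum
#' distance, a fully lowered wing (-90 deg) the maximum. The vector sum of
#' the three channels therefore peaks at maximum wing elevation, i.e. at the
#' start of each downstroke.
#'
#' @inheritParams simulate_accelerometer
#' @return A `triax_trace` data frame sampled at the magnetometer rate.
#' @export
simulate_magnetometer <- function(motion, config) {
  stopifnot(inherits(motion, "wing_motion"), inherits(config, "sim_config"))
  if (config$magnet_distance[1] <= 0) stop("minimum magnet distance must be positive")
  t <- sample_times(config$duration, config$mag_rate,
                    config$rate_offset[["mag"]], config$timestamp_jitter)
  n <- length(t)
  rmin <- config$magnet_distance[1]; rmax <- config$magnet_distance[2]
  s <- (motion$elevation(t) + 90) / 180   # 0 = fully lowered, 1 = fully raised
  s <- pmin(pmax(s, 0), 1)
  r <- rmax - (rmax - rmin) * s
  mag <- config$magnet_moment / r^3
  e <- config$dipole_direction
  E <- config$earth_field
  sdn <- config$noise_sd[["mag"]]
  new_trace(t,
            E[1] + mag * e[1] + rnorm(n, 0, sdn),
            E[2] + mag * e[2] + rnorm(n, 0, sdn),
            E[3] + mag * e[3] + rnorm(n, 0, sdn),
            config$mag_rate, "field (arbitrary)",
            c(x = "x", y = "y", z = "z"))
}

#' Simulate the position track, barometric pressure and wind record
#'
#' Integrates the configured track segments: altitude accumulates each
#' segment's vertical speed, horizontal position accumulates the segment
#' groundspeed vector, pressure follows the standard-atmosphere formula
#' ([pressure_from_altitude()], the exact inverse of
#' [barometric_altitude()]), and wind is constant.
#'
#' @param config A [sim_config()].
#' @return A list with `track` (data frame `time`, `x`, `y`,
#'   `groundspeed_x`, `groundspeed_y` at the GPS rate), `pressure` (`time`,
#'   `pa`), `wind` (`time`, `wx`, `wy`) and `truth` (per-sample `altitude`,
#'   `v_z` and `airspeed` on the GPS timeline).
#' @export
simulate_track <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  segs <- config$track_segments
  durs <- vapply(segs, function(s) s$duration, numeric(1))
  starts <- cumsum(c(0, durs[-length(durs)]))
  ends <- cumsum(durs)
  alt_knots <- config$altitude0 +
    cumsum(c(0, vapply(segs, function(s) s$v_z, numeric(1)) * durs))

  seg_index <- function(t) pmin(findInterval(t, c(starts, config$duration + 1e-9)),
                                length(segs))
  alt_at <- function(t) {
    i <- seg_index(t)
    alt_knots[i] + vapply(segs, function(s) s$v_z, numeric(1))[i] * (t - starts[i])
  }

  tg <- seq(0, config$duration, by = 1 / config$gps_rate)
  i <- seg_index(tg)
  gsx <- vapply(segs, function(s) s$groundspeed[1], numeric(1))[i]
  gsy <- vapply(segs, function(s) s$groundspeed[2], numeric(1))[i]
  # position integrates piecewise-constant groundspeed from segment starts
  posx_knots <- cumsum(c(0, vapply(segs, function(s) s$groundspeed[1], numeric(1)) * durs))
  posy_knots <- cumsum(c(0, vapply(segs, function(s) s$groundspeed[2], numeric(1)) * durs))
  px <- posx_knots[i] + gsx * (tg - starts[i])
  py <- posy_knots[i] + gsy * (tg - starts[i])
  track <- data.frame(time = tg, x = px, y = py,
                      groundspeed_x = gsx, groundspeed_y = gsy)

  tp <- seq(0, config$duration, by = 1 / config$pressure_rate)
  pa <- pressure_from_altitude(alt_at(tp), config$reference_pressure) +
    rnorm(length(tp), 0, config$noise_sd[["pressure"]])
  pressure <- data.frame(time = tp, pa = pa)

  wind <- data.frame(time = 0, wx = config$wind[1], wy = config$wind[2])

  vz <- vapply(segs, function(s) s$v_z, numeric(1))[i]
  truth <- data.frame(time = tg, altitude = alt_at(tg), v_z = vz,
                      airspeed = sqrt((gsx - config$wind[1])^2 +
                                      (gsy - config$wind[2])^2))
  list(track = track, pressure = pressure, wind = wind, truth = truth)
}

#' Run the full forward simulation
#'
#' Seeds the RNG from the config and generates the wing motion and all four
#' sensor streams plus ground truth. Identical configs (including seed) give
#' bit-identical output.
#'
#' @param config A [sim_config()].
#' @return An object of class `flight_sim`: a list with elements `accel`,
#'   `mag` (tri-axial traces), `track`, `pressure`, `wind` (data frames),
#'   `motion` (the `wing_motion`), `truth` (list of `cycles` and `state`
#'   ground-truth tables) and `config`.
#' @examples
#' sim <- simulate_flight(sim_config(duration = 5))
#' sim
#' @export
simulate_flight <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  motion <- simulate_wing_motion(config)
  accel <- simulate_accelerometer(motion, config)
  mag <- simulate_magnetometer(motion, config)
  trk <- simulate_track(config)
  structure(list(accel = accel, mag = mag, track = trk$track,
                 pressure = trk$pressure, wind = trk$wind,
                 motion = motion,
                 truth = list(cycles = motion$cycles, state = trk$truth),
                 config = config),
            class = "flight_sim")
}

#' @export
print.flight_sim <- function(x, ...) {
  cat(sprintf("<flight_sim> %g s | %d accel samples @ %g Hz | %d mag samples @ %g Hz | %d true cycles\n",
              x$config$duration, nrow(x$accel), x$config$accel_rate,
              nrow(x$mag), x$config$mag_rate, nrow(x$truth$cycles)))
  invisible(x)
}

#' Write a simulation to disk as CSV streams plus ground-truth JSON
#'
#' Emits one CSV per sensor stream (`accel.csv`, `mag.csv`, `track.csv`,
#' `pressure.csv`, `wind.csv`) and `ground_truth.json`.
#'
#' @param sim A `flight_sim` from [simulate_flight()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "flight_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  a <- sim$accel; names(a) <- c("time", "ax", "ay", "az")
  m <- sim$mag; names(m) <- c("time", "mx", "my", "mz")
  write.csv(a, file.path(dir, "accel.csv"), row.names = FALSE)
  write.csv(m, file.path(dir, "mag.csv"), row.names = FALSE)
  tr <- sim$track
  tr$altitude <- approx(sim$truth$state$time, sim$truth$state$altitude,
                        xout = tr$time, rule = 2)$y
  write.csv(tr[, c("time", "x", "y", "altitude", "groundspeed_x", "groundspeed_y")],
            file.path(dir, "track.csv"), row.names = FALSE)
  write.csv(sim$pressure, file.path(dir, "pressure.csv"), row.names = FALSE)
  write.csv(sim$wind, file.path(dir, "wind.csv"), row.names = FALSE)
  jsonlite::write_json(list(cycles = sim$truth$cycles, state = sim$truth$state),
                       file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
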