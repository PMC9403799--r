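#' Configuration for the flapping-flight simulator
#'
#' Collects every knob of the forward model in one validated object. Defaults
#' emulate a mid-sized flapping bird (wingbeat frequency 5 Hz, peak-to-peak
#' wing elevation 90 degrees) carrying a back-mounted logger that samples
#' acceleration at 100 Hz, magnetic field at 100 Hz, position at 1 Hz and
#' barometric pressure at 4 Hz, flying a single level track segment at
#' 12 m/s groundspeed in still air.
#'
#' @param duration Simulation length in seconds.
#' @param accel_rate,mag_rate,gps_rate,pressure_rate Nominal sampling rates
#'   (Hz) of the four sensor streams; all must be positive.
#' @param wingbeat_frequency Wingbeat frequency profile (Hz): a single value
#'   (constant), a length-2 vector `c(from, to)` (linear ramp over the
#'   duration), or a function of time.
#' @param wing_amplitude Peak-to-peak wing elevation profile (degrees), same
#'   forms as `wingbeat_frequency`. Must be non-negative.
#' @param downstroke_fraction Fraction of the wingbeat period spent in the
#'   downstroke, strictly between 0 and 1. The default 0.5 (symmetric
#'   strokes, which makes the heave waveform exactly sinusoidal) is a neutral
#'   choice; cruising birds are close to symmetric and stroke asymmetry is
#'   rarely quantified.
#' @param heave_gain Calibration constant translating downward wing angular
#'   velocity (rad/s) into dynamic heave acceleration (g). The default 0.04
#'   yields a peak-to-peak heave of roughly 2 g at the default kinematics,
#'   matching the signal size typical of back-mounted tags.
#' @param glide_bouts List of `c(start, end)` times (s) during which flapping
#'   pauses: the wing freezes at its current elevation and no wingbeat cycles
#'   accrue.
#' @param track_segments List of segments tiling the duration, each a list
#'   with `mode` ("level", "climb" or "descent"), `v_z` (vertical speed,
#'   m/s), `groundspeed` (length-2 horizontal vector, m/s) and `duration`
#'   (s).
#' @param wind Constant horizontal wind vector (m/s, to-direction).
#' @param magnet_moment Strength of the wing-mounted magnet (arbitrary field
#'   units times m^3); 0 disables the magnet.
#' @param magnet_distance Length-2 vector `c(min, max)`: magnet-to-sensor
#'   distance (m) when the wing is fully raised (+90 deg) and fully lowered
#'   (-90 deg). `min` must be positive and smaller than `max`.
#' @param earth_field Constant geomagnetic field vector (arbitrary units).
#' @param dipole_direction Unit vector along which the magnet's field adds to
#'   the earth field. Must satisfy `sum(dipole_direction * earth_field) >= 0`
#'   so the vector sum increases monotonically with the magnet term; the
#'   default is aligned with `earth_field`.
#' @param noise_sd Named numeric vector of i.i.d. Gaussian noise standard
#'   deviations per stream: `accel` (g), `mag` (field units), `pressure`
#'   (Pa).
#' @param rate_offset Named numeric vector (`accel`, `mag`): difference
#'   between the true and nominal sampling rate in Hz (biologgers commonly
#'   run up to ~3 Hz off nominal). Timestamps are truthful; only the nominal
#'   rate lies.
#' @param timestamp_jitter Uniform jitter applied to each timestamp, as a
#'   fraction of the sampling interval in (0, 0.5); 0 disables jitter.
#' @param altitude0 Initial altitude (m).
#' @param reference_pressure Sea-level pressure (Pa) used to generate the
#'   barometric stream.
#' @param seed Integer seed making the simulation reproducible.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_flight()]
#' @export
sim_config <- function(duration = 60,
                       accel_rate = 100, mag_rate = 100,
                       gps_rate = 1, pressure_rate = 4,
                       wingbeat_frequency = 5,
                       wing_amplitude = 90,
                       downstroke_fraction = 0.5,
                       heave_gain = 0.04,
                       glide_bouts = list(),
                       track_segments = NULL,
                       wind = c(0, 0),
                       magnet_moment = 0.004,
                       magnet_distance = c(0.05, 0.12),
                       earth_field = c(20, 0, -43),
                       dipole_direction = NULL,
                       noise_sd = c(accel = 0, mag = 0, pressure = 0),
                       rate_offset = c(accel = 0, mag = 0),
                       timestamp_jitter = 0,
                       altitude0 = 0,
                       reference_pressure = 101325,
                       seed = 1L) {
  if (is.null(track_segments)) {
    track_segments <- list(list(mode = "level", v_z = 0,
                                groundspeed = c(12, 0), duration = duration))
  }
  nz <- c(accel = 0, mag = 0, pressure = 0)
  nz[names(noise_sd)] <- noise_sd
  ro <- c(accel = 0, mag = 0)
  ro[names(rate_offset)] <- rate_offset
  if (is.null(dipole_direction)) {
    dipole_direction <- earth_field / sqrt(sum(earth_field^2))
  }
  cfg <- structure(list(
    duration = duration,
    accel_rate = accel_rate, mag_rate = mag_rate,
    gps_rate = gps_rate, pressure_rate = pressure_rate,
    wingbeat_frequency = wingbeat_frequency,
    wing_amplitude = wing_amplitude,
    downstroke_fraction = downstroke_fraction,
    heave_gain = heave_gain,
    glide_bouts = glide_bouts,
    track_segments = track_segments,
    wind = wind,
    magnet_moment = magnet_moment,
    magnet_distance = magnet_distance,
    earth_field = earth_field,
    dipole_direction = dipole_direction,
    noise_sd = nz,
    rate_offset = ro,
    timestamp_jitter = timestamp_jitter,
    altitude0 = altitude0,
    reference_pressure = reference_pressure,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  rates <- c(cfg$accel_rate, cfg$mag_rate, cfg$gps_rate, cfg$pressure_rate)
  if (!all(is.finite(rates)) || any(rates <= 0)) {
    stop("all sampling rates must be positive")
  }
  if (cfg$duration <= 0) stop("duration must be positive")
  if (cfg$downstroke_fraction <= 0 || cfg$downstroke_fraction >= 1) {
    stop("downstroke_fraction must lie strictly between 0 and 1")
  }
  amp <- profile_values(cfg$wing_amplitude,
                        seq(0, cfg$duration, length.out = 201))
  if (any(amp < 0)) stop("wing amplitude profile must be non-negative")
  frq <- profile_values(cfg$wingbeat_frequency,
                        seq(0, cfg$duration, length.out = 201))
  if (any(frq < 0)) stop("wingbeat frequency profile must be non-negative")
  if (cfg$magnet_distance[1] <= 0) stop("minimum magnet distance must be positive")
  if (cfg$magnet_distance[1] >= cfg$magnet_distance[2]) {
    stop("magnet_distance must satisfy min < max")
  }
  if (sum(cfg$dipole_direction * cfg$earth_field) < 0) {
    stop("dipole_direction must not oppose earth_field (vector sum would not be monotone in the dipole term)")
  }
  if (cfg$timestamp_jitter < 0 || cfg$timestamp_jitter >= 0.5) {
    stop("timestamp_jitter must lie in [0, 0.5)")
  }
  for (b in cfg$glide_bouts) {
    if (length(b) != 2 || b[1] >= b[2]) stop("glide bouts must be c(start, end) with start < end")
  }
  dur <- sum(vapply(cfg$track_segments, function(s) s$duration, numeric(1)))
  if (abs(dur - cfg$duration) > 1e-8) {
    stop("track segments must tile the full duration (got ", dur,
         " s of segments for a ", cfg$duration, " s simulation)")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  duration: %g s; rates (Hz): accel %g, mag %g, gps %g, pressure %g\n",
              x$duration, x$accel_rate, x$mag_rate, x$gps_rate, x$pressure_rate))
  cat(sprintf("  wingbeat: f = %s Hz, amplitude = %s deg (peak-to-peak), downstroke fraction %g\n",
              profile_label(x$wingbeat_frequency), profile_label(x$wing_amplitude),
              x$downstroke_fraction))
  cat(sprintf("  glide bouts: %d; track segments: %d; seed %d\n",
              length(x$glide_bouts), length(x$track_segments), x$seed))
  invisible(x)
}

# Evaluate a profile (scalar, c(from, to) ramp, or function of time) at times t.
profile_values <- function(profile, t, duration = max(t)) {
  if (is.function(profile)) return(profile(t))
  if (length(profile) == 1) return(rep(profile, length(t)))
  if (length(profile) == 2) {
    return(profile[1] + (profile[2] - profile[1]) * t / duration)
  }
  stop("a profile must be a scalar, a length-2 ramp c(from, to), or a function of time")
}

profile_label <- function(profile) {
  if (is.function(profile)) return("f(t)")
  if (length(profile) == 1) return(format(profile))
  paste0(format(profile[1]), "->", format(profile[2]))
}
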