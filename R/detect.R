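#' Detection parameters for wingbeat peak finding
#'
#' @param smooth_window Centered moving-average window (samples) applied to
#'   the raw heave signal before peak detection. Must be odd; 1 disables
#'   smoothing (appropriate for high wingbeat frequencies relative to the
#'   sampling rate, where the raw signal is already clean). Field data are
#'   typically smoothed over 3-5 points; heavily oversampled signals warrant
#'   wider windows (see [suggest_smooth_window()]).
#' @param derivative_threshold Threshold on the magnitude of the second
#'   difference of the smoothed heave near a candidate peak. `NULL` (default)
#'   selects it automatically per bout via [auto_threshold()]; 0 disables
#'   thresholding entirely.
#' @param threshold_quantile Quantile used by [auto_threshold()] when
#'   `derivative_threshold` is `NULL`.
#' @param search_radius Samples around a turning point searched for a
#'   super-threshold second difference, and the radius within which competing
#'   candidate peaks are resolved to the larger heave value.
#' @param min_frequency,max_frequency Plausible wingbeat frequency bounds
#'   (Hz) for [filter_outlier_cycles()]. `NULL` defaults to 0.5-2 times the
#'   median frequency of the bout.
#' @param min_separation Minimum separation (samples) between detected
#'   peaks; competing peaks closer than this are resolved to the larger
#'   heave value. Defaults to `search_radius`. Should be somewhat below the
#'   shortest plausible wingbeat period in samples
#'   (`sampling_rate / max_frequency`); see [suggest_detection_params()].
#' @param block_size Number of consecutive cycles averaged per interval by
#'   [average_intervals()] (10 for field data; 5 suits short wind-tunnel
#'   bouts).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(smooth_window = 5,
                             derivative_threshold = NULL,
                             threshold_quantile = 0.9,
                             search_radius = 5,
                             min_frequency = NULL,
                             max_frequency = NULL,
                             min_separation = NULL,
                             block_size = 10) {
  if (smooth_window < 1 || smooth_window %% 2 == 0) {
    stop("smooth_window must be odd and >= 1")
  }
  if (!is.null(min_frequency) && !is.null(max_frequency) &&
      min_frequency >= max_frequency) {
    stop("min_frequency must be below max_frequency")
  }
  if (block_size < 1) stop("block_size must be >= 1")
  structure(list(smooth_window = as.integer(smooth_window),
                 derivative_threshold = derivative_threshold,
                 threshold_quantile = threshold_quantile,
                 search_radius = as.integer(search_radius),
                 min_frequency = min_frequency,
                 max_frequency = max_frequency,
                 min_separation = if (!is.null(min_separation))
                   as.integer(min_separation),
                 block_size = as.integer(block_size)),
            class = "detection_params")
}

#' Detection parameters matched to a sampling rate and expected frequency
#'
#' Convenience constructor mirroring per-bout tuning practice: the smoothing
#' window spans about a third of the expected wingbeat period
#' ([suggest_smooth_window()]), plausible frequencies are bounded by 0.5-2
#' times the expected frequency, the minimum peak separation is 60% of the
#' expected period, and the second-difference threshold is the per-bout
#' median (within a pure flapping bout, wingbeat curvature dominates half the
#' samples; the higher 0.9 default of [auto_threshold()] suits mixed
#' recordings where flapping is a minority of samples).
#'
#' @param sampling_rate Heave sampling rate (Hz).
#' @param expected_frequency Rough expected wingbeat frequency (Hz).
#' @param ... Overrides passed on to [detection_params()].
#' @return A [detection_params()] object.
#' @export
suggest_detection_params <- function(sampling_rate, expected_frequency, ...) {
  over <- list(...)
  args <- list(
    smooth_window = suggest_smooth_window(sampling_rate, expected_frequency),
    threshold_quantile = 0.5,
    min_frequency = 0.5 * expected_frequency,
    max_frequency = 2 * expected_frequency,
    min_separation = max(1L, as.integer(floor(
      0.6 * sampling_rate / expected_frequency)))
  )
  args[names(over)] <- over
  do.call(detection_params, args)
}

#' Centered moving average with truncated edges
#'
#' Smooths a series with a centered window of `window` samples; near the
#' edges the window is truncated to the available samples. `window = 1`
#' returns the input unchanged. Interior samples of a linear trend are
#' preserved exactly.
#'
#' @param x Numeric series.
#' @param window Odd integer window length, `1 <= window <= length(x)`.
#' @return Smoothed series of the same length.
#' @export
smooth_signal <- function(x, window) {
  n <- length(x)
  if (window %% 2 == 0) stop("window must be odd")
  if (window < 1 || window > n) stop("window must lie in [1, length(x)]")
  if (window == 1) return(x)
  h <- (window - 1L) / 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Pick a smoothing window matched to the sampling rate
#'
#' A window spanning roughly a third of the expected wingbeat period keeps
#' the wingbeat waveform (attenuation below ~20%) while suppressing sample
#' level noise; it reproduces the conventional 3-5 point windows at ~40 Hz
#' sampling of a ~4 Hz wingbeat and widens appropriately for oversampled
#' signals. Signals with fewer than ~6 samples per cycle are left unsmoothed
#' (high wingbeat frequencies at these rates give a clean signal that
#' smoothing would only blur).
#'
#' @param sampling_rate Sampling rate of the heave signal (Hz).
#' @param expected_frequency Rough expected wingbeat frequency (Hz).
#' @return An odd integer window length.
#' @export
suggest_smooth_window <- function(sampling_rate, expected_frequency) {
  spc <- sampling_rate / expected_frequency
  if (spc < 6) return(1L)
  max(3L, odd_floor(spc / 3))
}

#' Automatic second-difference threshold
#'
#' Returns a quantile (default 0.90) of the absolute second difference of
#' the series — a deterministic, scale-equivariant stand-in for the manual
#' per-bout threshold selection used with field data.
#'
#' @param x Numeric series containing flapping signal.
#' @param quantile_level Quantile of `|diff(x, differences = 2)|` to return.
#' @return Threshold in signal units.
#' @export
auto_threshold <- function(x, quantile_level = 0.9) {
  if (length(x) < 3) stop("series too short for a second difference")
  d2 <- diff(x, differences = 2)
  if (all(d2 == 0)) stop("series has no curvature: no flapping signal to threshold")
  unname(quantile(abs(d2), quantile_level, names = FALSE))
}

#' Detect downstroke peaks in the heave acceleration
#'
#' Implements the wingbeat peak detector: the heave series is smoothed
#' (centered moving average), positive-to-negative turning points of the
#' first difference mark candidate peaks, and a candidate is accepted when
#' the magnitude of the second difference exceeds the threshold within
#' `search_radius` samples of the turning point. Accepted candidates closer
#' together than `search_radius` samples are resolved to the one with the
#' larger (smoothed) heave value. With a threshold of 0, the detector returns
#' exactly the local maxima of the smoothed series.
#'
#' @param heave Raw heave series (g); smoothing is applied internally
#'   according to `params$smooth_window`.
#' @param params A [detection_params()] object.
#' @return Integer indices of detected peaks (positions in `heave`). A series
#'   too short to contain a turning point yields an empty result with a
#'   warning.
#' @export
detect_wingbeat_peaks <- function(heave, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  n <- length(heave)
  if (n < 3) {
    warning("series too short for peak detection (", n, " samples)")
    return(integer())
  }
  s <- smooth_signal(heave, params$smooth_window)
  d1 <- diff(s)
  # positive-to-negative turning points; plateaus (zero first differences)
  # take the sign of the next nonzero difference, so a rise-plateau-fall
  # peaks at the first plateau sample and a rise onto a terminal or
  # glide-entry plateau is not a peak
  sgn <- sign(d1)
  zi <- which(sgn == 0)
  for (i in rev(zi)) sgn[i] <- if (i < length(sgn)) sgn[i + 1L] else 0
  cand <- which(d1[-(n - 1L)] > 0 & sgn[-1L] < 0) + 1L
  if (length(cand) == 0) return(integer())

  thr <- params$derivative_threshold
  if (is.null(thr)) thr <- auto_threshold(s, params$threshold_quantile)
  if (thr > 0) {
    d2 <- diff(s, differences = 2)  # d2[j] is centered on sample j + 1
    r <- params$search_radius
    ok <- vapply(cand, function(i) {
      j <- max(1L, i - 1L - r):min(length(d2), i - 1L + r)
      any(abs(d2[j]) >= thr)
    }, logical(1))
    cand <- cand[ok]
    cand <- resolve_close_peaks(cand, s,
                                params$min_separation %||% params$search_radius)
  }
  cand
}

# Greedy non-maximum suppression: among accepted candidates closer together
# than `radius` samples, keep the one with the larger smoothed heave.
resolve_close_peaks <- function(idx, s, radius) {
  if (length(idx) < 2) return(idx)
  ord <- idx[order(s[idx], idx, decreasing = TRUE)]
  kept <- integer()
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= radius)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Magnetometer vector sum
#'
#' Per-sample Euclidean norm of the three magnetometer channels. The norm is
#' invariant to sensor-frame rotation and, with a wing-mounted magnet, varies
#' solely with the magnet-sensor distance.
#'
#' @param mag A `triax_trace` (or any data frame with columns `x`, `y`, `z`).
#' @return Numeric vector of the same length as the trace.
#' @export
mag_vector_sum <- function(mag) {
  stopifnot(all(c("x", "y", "z") %in% names(mag)))
  sqrt(mag$x^2 + mag$y^2 + mag$z^2)
}
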