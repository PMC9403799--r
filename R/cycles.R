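#' Segment detected peaks into wingbeat cycles
#'
#' Each pair of consecutive peaks delimits one wingbeat cycle, half-open
#' `[peak_i, peak_{i+1})`. Period and frequency are computed from the actual
#' timestamps, not the nominal sampling rate, so loggers whose true rate
#' deviates from nominal (commonly by up to ~3 Hz) are handled correctly.
#'
#' @param peaks Integer indices of detected peaks.
#' @param time Timestamps (s) of the heave series the peaks refer to.
#' @return A data frame of cycles: `start_time`, `end_time`, `period`,
#'   `frequency`, `start_index`, `end_index`. Fewer than 2 peaks give an
#'   empty table.
#' @export
segment_wingbeats <- function(peaks, time) {
  if (length(peaks) < 2) {
    return(data.frame(start_time = numeric(), end_time = numeric(),
                      period = numeric(), frequency = numeric(),
                      start_index = integer(), end_index = integer()))
  }
  st <- time[peaks[-length(peaks)]]
  en <- time[peaks[-1]]
  data.frame(start_time = st, end_time = en,
             period = en - st, frequency = 1 / (en - st),
             start_index = peaks[-length(peaks)],
             end_index = peaks[-1])
}

#' Heave amplitude of one cycle window
#'
#' Difference between the highest and lowest heave values in the window —
#' computed on the raw (unsmoothed) heave signal.
#'
#' @param window Numeric vector of raw heave values over one cycle.
#' @return Non-negative amplitude (g).
#' @export
heave_amplitude <- function(window) {
  if (!length(window)) stop("empty cycle window")
  max(window) - min(window)
}

# Per-cycle heave amplitude over half-open windows [start_index, end_index).
cycle_heave_amplitudes <- function(heave, cycles) {
  vapply(seq_len(nrow(cycles)), function(k) {
    heave_amplitude(heave[cycles$start_index[k]:(cycles$end_index[k] - 1L)])
  }, numeric(1))
}

#' Remove cycles with implausible frequencies
#'
#' Drops cycles whose frequency falls outside `[min_frequency,
#' max_frequency]`. When bounds are not set, they default to 0.5 and 2 times
#' the median frequency of the bout — low outliers typically arise from
#' undetected glide gaps, high outliers from false peaks during manoeuvres.
#' The counts removed below and above the band are attached as the
#' `"removed"` attribute.
#'
#' @param cycles Cycle table from [segment_wingbeats()].
#' @param params Optional [detection_params()] carrying the bounds.
#' @param min_frequency,max_frequency Explicit bounds (Hz), overriding
#'   `params`.
#' @return The filtered cycle table with attribute `removed = c(low, high)`.
#' @export
filter_outlier_cycles <- function(cycles, params = NULL,
                                  min_frequency = NULL, max_frequency = NULL) {
  if (!is.null(params)) {
    min_frequency <- min_frequency %||% params$min_frequency
    max_frequency <- max_frequency %||% params$max_frequency
  }
  if (nrow(cycles) == 0) {
    attr(cycles, "removed") <- c(low = 0L, high = 0L)
    return(cycles)
  }
  med <- median(cycles$frequency)
  lo <- min_frequency %||% (0.5 * med)
  hi <- max_frequency %||% (2 * med)
  low <- cycles$frequency < lo
  high <- cycles$frequency > hi
  out <- cycles[!(low | high), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(low = sum(low), high = sum(high))
  out
}

#' Average cycles over fixed-size blocks
#'
#' Groups consecutive cycles into non-overlapping blocks of exactly
#' `block_size` cycles (10 for field data, 5 for short wind-tunnel bouts);
#' the trailing incomplete block is dropped. Means are arithmetic.
#'
#' @param cycles Filtered cycle table (with `heave_amplitude` and optionally
#'   `peak_mag_vsum` columns added).
#' @param block_size Cycles per interval, >= 1.
#' @return A data frame of intervals: `start`, `end`, `n_cycles`,
#'   `mean_frequency`, `mean_heave_amplitude` and, when available,
#'   `mean_peak_mag`.
#' @export
average_intervals <- function(cycles, block_size = 10) {
  if (block_size < 1) stop("block_size must be >= 1")
  block_size <- as.integer(block_size)
  nb <- nrow(cycles) %/% block_size
  if (nb == 0) {
    out <- data.frame(start = numeric(), end = numeric(),
                      n_cycles = integer(), mean_frequency = numeric(),
                      mean_heave_amplitude = numeric())
    if (!is.null(cycles$peak_mag_vsum)) out$mean_peak_mag <- numeric()
    return(out)
  }
  g <- rep(seq_len(nb), each = block_size)
  used <- cycles[seq_along(g), , drop = FALSE]
  out <- data.frame(
    start = tapply(used$start_time, g, min),
    end = tapply(used$end_time, g, max),
    n_cycles = as.integer(tapply(used$frequency, g, length)),
    mean_frequency = as.numeric(tapply(used$frequency, g, mean)),
    mean_heave_amplitude = if (!is.null(used$heave_amplitude))
      as.numeric(tapply(used$heave_amplitude, g, mean)) else NA_real_
  )
  if (!is.null(used$peak_mag_vsum)) {
    out$mean_peak_mag <- as.numeric(tapply(used$peak_mag_vsum, g, mean))
  }
  rownames(out) <- NULL
  out
}

#' Peak magnetometer vector sum per cycle
#'
#' Assigns magnetometer samples to cycles by timestamp membership in the
#' half-open span `[start_time, end_time)` and takes the per-cycle maximum of
#' the vector sum. No interpolation is performed: cycles containing no
#' magnetometer sample (possible when the magnetometer rate undersamples the
#' wingbeat) get `NA` and should be excluded from amplitude-proxy fits.
#'
#' @param time Timestamps of the vector-sum series.
#' @param vsum Vector-sum series from [mag_vector_sum()].
#' @param cycles Cycle table.
#' @return `cycles` with a `peak_mag_vsum` column added.
#' @export
peak_mag_per_cycle <- function(time, vsum, cycles) {
  stopifnot(length(time) == length(vsum))
  if (nrow(cycles) == 0) {
    cycles$peak_mag_vsum <- numeric()
    return(cycles)
  }
  if (min(time) >= max(cycles$end_time) || max(time) < min(cycles$start_time)) {
    stop("magnetometer time range does not overlap the cycle spans")
  }
  cycles$peak_mag_vsum <- vapply(seq_len(nrow(cycles)), function(k) {
    inw <- vsum[time >= cycles$start_time[k] & time < cycles$end_time[k]]
    if (length(inw)) max(inw) else NA_real_
  }, numeric(1))
  cycles
}

#' Detect and quantify wingbeats in an acceleration trace
#'
#' The top-level detector: smooths the heave channel, finds downstroke peaks
#' ([detect_wingbeat_peaks()]), segments cycles ([segment_wingbeats()]),
#' computes per-cycle heave amplitude on the raw signal, optionally attaches
#' the per-cycle peak magnetometer vector sum, and removes
#' implausible-frequency cycles ([filter_outlier_cycles()]).
#'
#' @param accel A `triax_trace` (or data frame with `time` and the heave
#'   column).
#' @param params A [detection_params()] object.
#' @param mag Optional magnetometer `triax_trace` for the amplitude proxy.
#' @param heave_col Name of the heave (dorsoventral) channel in `accel`.
#' @return An object of class `wingbeats`: a list with `cycles` (the
#'   filtered per-cycle table), `all_cycles`, `peaks` (indices), `threshold`
#'   used, `params`, and `counts` (detected / removed-low / removed-high /
#'   retained).
#' @examples
#' sim <- simulate_flight(sim_config(duration = 10))
#' wb <- wingbeats(sim$accel, detection_params(smooth_window = 5), mag = sim$mag)
#' wb
#' @export
wingbeats <- function(accel, params = detection_params(), mag = NULL,
                      heave_col = "z") {
  stopifnot(heave_col %in% names(accel), "time" %in% names(accel))
  heave <- accel[[heave_col]]
  peaks <- detect_wingbeat_peaks(heave, params)
  thr <- params$derivative_threshold
  if (is.null(thr) && length(peaks)) {
    thr <- auto_threshold(smooth_signal(heave, params$smooth_window),
                          params$threshold_quantile)
  }
  cycles <- segment_wingbeats(peaks, accel$time)
  if (nrow(cycles)) cycles$heave_amplitude <- cycle_heave_amplitudes(heave, cycles)
  if (!is.null(mag) && nrow(cycles)) {
    cycles <- peak_mag_per_cycle(mag$time, mag_vector_sum(mag), cycles)
  }
  filtered <- filter_outlier_cycles(cycles, params)
  structure(list(
    cycles = filtered,
    all_cycles = cycles,
    peaks = peaks,
    threshold = thr,
    params = params,
    counts = c(detected = nrow(cycles),
               removed_low = unname(attr(filtered, "removed")["low"]),
               removed_high = unname(attr(filtered, "removed")["high"]),
               retained = nrow(filtered))
  ), class = "wingbeats")
}

#' @export
print.wingbeats <- function(x, ...) {
  cat(sprintf("<wingbeats> %d peaks -> %d cycles (%d retained after frequency filter)\n",
              length(x$peaks), x$counts["detected"], x$counts["retained"]))
  if (nrow(x$cycles)) {
    cat(sprintf("  frequency: %.3g +/- %.2g Hz | heave amplitude: %.3g +/- %.2g g\n",
                mean(x$cycles$frequency), sd(x$cycles$frequency),
                mean(x$cycles$heave_amplitude), sd(x$cycles$heave_amplitude)))
  }
  invisible(x)
}

#' @export
summary.wingbeats <- function(object, ...) {
  cy <- object$cycles
  out <- list(
    n_cycles = nrow(cy),
    counts = object$counts,
    threshold = object$threshold,
    mean_frequency = if (nrow(cy)) mean(cy$frequency) else NA_real_,
    # bout-level estimator: cycles per unit flapping time; immune to the
    # upward Jensen bias of averaging 1/period under peak-time quantization
    bout_frequency = if (nrow(cy)) nrow(cy) / sum(cy$period) else NA_real_,
    sd_frequency = if (nrow(cy) > 1) sd(cy$frequency) else NA_real_,
    mean_heave_amplitude = if (nrow(cy)) mean(cy$heave_amplitude) else NA_real_,
    sd_heave_amplitude = if (nrow(cy) > 1) sd(cy$heave_amplitude) else NA_real_,
    cv_frequency = if (nrow(cy) > 1) sd(cy$frequency) / mean(cy$frequency) else NA_real_
  )
  class(out) <- "summary.wingbeats"
  out
}

#' @export
print.summary.wingbeats <- function(x, ...) {
  cat("Wingbeat detection summary\n")
  cat(sprintf("  cycles: %d retained (%d detected, %d low / %d high removed)\n",
              x$n_cycles, x$counts["detected"], x$counts["removed_low"],
              x$counts["removed_high"]))
  cat(sprintf("  threshold (|2nd diff|): %.4g\n", x$threshold))
  cat(sprintf("  frequency: %.4g +/- %.3g Hz (CV %.3g)\n",
              x$mean_frequency, x$sd_frequency, x$cv_frequency))
  cat(sprintf("  heave amplitude: %.4g +/- %.3g g\n",
              x$mean_heave_amplitude, x$sd_heave_amplitude))
  invisible(x)
}

#' Plot detected wingbeats over the heave signal
#'
#' @param x A `wingbeats` object.
#' @param accel The acceleration trace it was computed from.
#' @param heave_col Heave column name.
#' @param xlim Optional time window to display.
#' @param ... Passed to `plot`.
#' @export
plot.wingbeats <- function(x, accel, heave_col = "z", xlim = NULL, ...) {
  t <- accel$time; h <- accel[[heave_col]]
  if (is.null(xlim)) xlim <- range(t)
  keep <- t >= xlim[1] & t <= xlim[2]
  plot(t[keep], h[keep], type = "l", xlab = "time (s)", ylab = "heave (g)",
       ...)
  pk <- x$peaks[t[x$peaks] >= xlim[1] & t[x$peaks] <= xlim[2]]
  points(t[pk], h[pk], col = 2, pch = 19)
  invisible(x)
}
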