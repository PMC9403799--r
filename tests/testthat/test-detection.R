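test_that("moving-average smoothing follows the truncated-edge rule", {
  expect_equal(smooth_signal(rep(4, 10), 5), rep(4, 10))
  expect_equal(smooth_signal(c(0, 3, 0, 3, 0), 3), c(1.5, 1, 2, 1, 1.5))
  # interior of a linear ramp is unchanged
  x <- seq(0, 9)
  expect_equal(smooth_signal(x, 3)[2:9], x[2:9])
  # window 1 is the identity
  expect_identical(smooth_signal(c(5, 1, 7), 1), c(5, 1, 7))
  expect_error(smooth_signal(1:10, 4), "odd")
  expect_error(smooth_signal(1:3, 5), "length")
})

test_that("auto threshold is the stated quantile and scales with the signal", {
  # second differences on a known grid: oracle by sorting
  x <- cumsum(cumsum(c(0, 0, rep(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), 3))))
  d2 <- diff(x, differences = 2)
  expect_equal(auto_threshold(x, 0.9),
               unname(quantile(abs(d2), 0.9, names = FALSE)))
  expect_equal(auto_threshold(3.7 * x), 3.7 * auto_threshold(x))
  expect_error(auto_threshold(rep(2, 50)), "no flapping|no curvature")
})

test_that("peak detection finds sinusoid maxima and nothing in flat series", {
  t <- seq(0, 2, by = 0.01)
  h <- 1 + sin(2 * pi * 5 * t - pi / 2)
  p <- detection_params(smooth_window = 1, derivative_threshold = 0)
  pk <- detect_wingbeat_peaks(h, p)
  expect_identical(length(pk), 10L)
  # peaks at the sinusoid maxima (t = 0.1, 0.3, ...)
  expect_equal(t[pk], seq(0.1, 1.9, by = 0.2), tolerance = 1e-9)
  expect_identical(detect_wingbeat_peaks(rep(1, 100), p), integer())
  expect_warning(out <- detect_wingbeat_peaks(c(1, 2), p), "short")
  expect_identical(out, integer())
})

test_that("with threshold zero the detector equals the local-maximum oracle", {
  p <- detection_params(smooth_window = 1, derivative_threshold = 0)
  set.seed(101)
  for (rep in 1:20) {
    x <- cumsum(rnorm(500)) + sin(seq(0, 20, length.out = 500))
    expect_identical(detect_wingbeat_peaks(x, p), local_max_oracle(x))
  }
  # and on smoothed noisy sinusoids, with the same smoothing applied to both
  set.seed(202)
  t <- seq(0, 5, by = 0.01)
  x <- 1 + sin(2 * pi * 4 * t) + rnorm(length(t), 0, 0.1)
  p5 <- detection_params(smooth_window = 5, derivative_threshold = 0)
  expect_identical(detect_wingbeat_peaks(x, p5),
                   local_max_oracle(smooth_signal(x, 5)))
})

test_that("cycle segmentation uses actual timestamps, not the nominal rate", {
  # peaks every 20 samples at a true 100 Hz
  pk <- seq(1, 201, by = 20)
  cy <- segment_wingbeats(pk, (0:220) / 100)
  expect_equal(cy$period, rep(0.2, 10))
  expect_equal(cy$frequency, rep(5, 10))
  # nominal 40 Hz logger actually running at 43 Hz
  cy43 <- segment_wingbeats(seq(1, 201, by = 20), (0:220) / 43)
  expect_equal(cy43$frequency, rep(43 / 20, 10), tolerance = 1e-12)
  # fewer than two peaks -> empty
  expect_identical(nrow(segment_wingbeats(c(7L), (0:10) / 10)), 0L)
})

test_that("per-cycle frequencies track a linear chirp", {
  cfg <- sim_config(duration = 30, accel_rate = 200,
                    wingbeat_frequency = c(4, 6), track_segments = list(
                      list(mode = "level", v_z = 0, groundspeed = c(10, 0),
                           duration = 30)))
  s <- simulate_flight(cfg)
  w <- wingbeats(s$accel, suggest_detection_params(200, 5))
  # oracle: instantaneous frequency of the chirp at each cycle midpoint
  mid <- (w$cycles$start_time + w$cycles$end_time) / 2
  f_true <- 4 + (6 - 4) * mid / 30
  expect_lt(max(abs(w$cycles$frequency - f_true) / f_true), 0.05)
})

test_that("heave amplitude is the raw within-cycle range", {
  expect_equal(heave_amplitude(c(0.8, 2.1, -0.3, 1.0)), 2.4)
  expect_equal(heave_amplitude(rep(0.7, 5)), 0)
  a <- sin(seq(0, 2 * pi, length.out = 1000)) * 1.3
  expect_equal(heave_amplitude(a), 2.6, tolerance = 1e-4)
  expect_error(heave_amplitude(numeric()), "empty")
})

test_that("outlier filter drops implausible frequencies and logs counts", {
  cy <- data.frame(start_time = 0:4, end_time = 1:5,
                   period = 1, frequency = c(5, 5.2, 0.1, 5.1, 40),
                   start_index = 1:5, end_index = 2:6)
  out <- filter_outlier_cycles(cy, min_frequency = 2, max_frequency = 10)
  expect_identical(nrow(out), 3L)
  expect_identical(attr(out, "removed"), c(low = 1L, high = 1L))
  # all within bounds -> unchanged
  ok <- filter_outlier_cycles(cy[cy$frequency < 10 & cy$frequency > 2, ],
                              min_frequency = 2, max_frequency = 10)
  expect_identical(nrow(ok), 3L)
  # default band is 0.5-2x the median
  cy2 <- cy
  cy2$frequency <- c(5, 5, 5, 5, 12)
  def <- filter_outlier_cycles(cy2)
  expect_identical(nrow(def), 4L)
})

test_that("interval averaging uses complete blocks and arithmetic means", {
  cy <- data.frame(start_time = seq(0, 4.8, by = 0.2),
                   end_time = seq(0.2, 5, by = 0.2),
                   period = 0.2, frequency = 5,
                   start_index = 1:25, end_index = 2:26,
                   heave_amplitude = runif(25, 1, 3))
  iv <- average_intervals(cy, 10)
  expect_identical(nrow(iv), 2L)
  expect_identical(iv$n_cycles, c(10L, 10L))
  expect_equal(iv$mean_frequency, c(5, 5))
  # direct-summation oracle for means
  expect_equal(iv$mean_heave_amplitude[1], sum(cy$heave_amplitude[1:10]) / 10)
  expect_equal(iv$mean_heave_amplitude[2], sum(cy$heave_amplitude[11:20]) / 10)
  # block accounting: sum of interval cycles <= filtered cycles
  expect_lte(sum(iv$n_cycles), nrow(cy))
  expect_identical(sum(iv$n_cycles), 10L * nrow(iv))
})

test_that("magnetometer vector sum is the Euclidean norm, rotation-invariant", {
  m <- data.frame(x = c(0, 3), y = c(0, 4), z = c(0, 0))
  expect_equal(mag_vector_sum(m), c(0, 5))
  set.seed(9)
  m2 <- data.frame(x = rnorm(50), y = rnorm(50), z = rnorm(50))
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- as.data.frame(as.matrix(m2) %*% R)
  names(rot) <- c("x", "y", "z")
  expect_equal(mag_vector_sum(rot), mag_vector_sum(m2), tolerance = 1e-12)
})

test_that("per-cycle magnetometer peaks match an exhaustive scan", {
  cy <- data.frame(start_time = c(0, 1, 2), end_time = c(1, 2, 3))
  tt <- seq(0, 2.99, by = 0.01)
  expect_equal(peak_mag_per_cycle(tt, rep(4, length(tt)), cy)$peak_mag_vsum,
               c(4, 4, 4))
  vs <- rep(1, length(tt)); vs[150] <- 7
  expect_equal(peak_mag_per_cycle(tt, vs, cy)$peak_mag_vsum, c(1, 7, 1))
  expect_error(peak_mag_per_cycle(tt + 100, vs, cy), "overlap")
  # simulated dipole trace vs scanning every sample per window
  s <- quiet_sim(duration = 5)
  w <- wingbeats(s$accel, suggest_detection_params(100, 5), mag = s$mag)
  vs2 <- mag_vector_sum(s$mag)
  oracle <- vapply(seq_len(nrow(w$cycles)), function(k) {
    max(vs2[s$mag$time >= w$cycles$start_time[k] &
            s$mag$time < w$cycles$end_time[k]])
  }, numeric(1))
  expect_equal(w$cycles$peak_mag_vsum, oracle)
})

test_that("frequency recovery holds across the plausible frequency range", {
  for (f in c(3, 6, 10)) {
    s <- simulate_flight(sim_config(duration = 15, accel_rate = 100,
                                    wingbeat_frequency = f, seed = 13))
    w <- wingbeats(s$accel, suggest_detection_params(100, f))
    expect_lt(abs(mean(w$cycles$frequency) - f) / f, 0.02)
  }
  # with noise, within 5%
  s <- simulate_flight(sim_config(duration = 15, accel_rate = 100,
                                  wingbeat_frequency = 6,
                                  noise_sd = c(accel = 0.2), seed = 13))
  w <- wingbeats(s$accel, suggest_detection_params(100, 6))
  expect_lt(abs(mean(w$cycles$frequency) - 6) / 6, 0.05)
})

test_that("detected heave amplitude rises with true wing amplitude and the mag proxy", {
  res <- lapply(c(50, 70, 90, 110), function(A) {
    s <- simulate_flight(sim_config(duration = 10, wing_amplitude = A,
                                    mag_rate = 50, seed = 31))
    w <- wingbeats(s$accel, suggest_detection_params(100, 5), mag = s$mag)
    w$cycles
  })
  mh <- vapply(res, function(x) mean(x$heave_amplitude), numeric(1))
  expect_true(all(diff(mh) > 0))
  d <- do.call(rbind, res)
  fit <- lm(heave_amplitude ~ peak_mag_vsum, d)
  expect_gt(coef(fit)[2], 0)
})
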