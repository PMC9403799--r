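test_that("config validation rejects impossible set-ups", {
  expect_error(sim_config(accel_rate = 0), "positive")
  expect_error(sim_config(downstroke_fraction = 1), "strictly between")
  expect_error(sim_config(wing_amplitude = -10), "non-negative")
  expect_error(sim_config(magnet_distance = c(0.1, 0.05)), "min < max")
  expect_error(sim_config(magnet_distance = c(0, 0.1)), "positive")
  expect_error(sim_config(track_segments = list(
    list(mode = "level", v_z = 0, groundspeed = c(10, 0), duration = 10))),
    "tile")
})

test_that("wing motion is periodic with the configured cycle structure", {
  # constant 5 Hz for 2 s -> exactly 10 complete cycles
  m <- simulate_wing_motion(sim_config(duration = 2, track_segments = list(
    list(mode = "level", v_z = 0, groundspeed = c(10, 0), duration = 2))))
  expect_identical(nrow(m$cycles), 10L)
  expect_equal(m$cycles$period, rep(0.2, 10), tolerance = 1e-9)

  # zero amplitude -> constant elevation everywhere
  m0 <- simulate_wing_motion(sim_config(duration = 2, wing_amplitude = 0,
                                        track_segments = list(
    list(mode = "level", v_z = 0, groundspeed = c(10, 0), duration = 2))))
  expect_equal(diff(range(m0$samples$elevation)), 0)

  # elevation bounded by +/- A/2 and downstroke samples have decreasing elevation
  cfg <- sim_config(duration = 2, wing_amplitude = 80, track_segments = list(
    list(mode = "level", v_z = 0, groundspeed = c(10, 0), duration = 2)))
  m2 <- simulate_wing_motion(cfg)
  expect_lte(max(abs(m2$samples$elevation)), 40 + 1e-9)
  el <- m2$samples$elevation
  down <- m2$samples$phase_label == "downstroke"
  dn <- which(down[-length(down)] & down[-1])
  expect_true(all(el[dn + 1] < el[dn]))
})

test_that("downstroke and upstroke durations follow downstroke_fraction", {
  # count samples per phase between elevation extrema (oracle: sample counting)
  cfg <- sim_config(duration = 4, wingbeat_frequency = 5,
                    downstroke_fraction = 0.4, accel_rate = 1000,
                    track_segments = list(list(mode = "level", v_z = 0,
                                               groundspeed = c(10, 0),
                                               duration = 4)))
  m <- simulate_wing_motion(cfg, rate = 1000)
  lab <- m$samples$phase_label
  frac_down <- mean(lab == "downstroke")
  expect_equal(frac_down, 0.4, tolerance = 0.01)
  # downstroke duration 0.4 * (1/5) = 0.08 s per cycle
  runs <- rle(lab)
  down_runs <- runs$lengths[runs$values == "downstroke"]
  expect_equal(median(down_runs) / 1000, 0.08, tolerance = 0.005)
})

test_that("accelerometer heave matches the kinematic model", {
  # zero amplitude, zero noise -> heave identically 1 g
  s0 <- quiet_sim(duration = 2, wing_amplitude = 0)
  expect_equal(s0$accel$z, rep(1, nrow(s0$accel)))
  expect_equal(s0$accel$x, rep(0, nrow(s0$accel)))

  # noiseless: heave peak at the downstroke midpoint within one sample
  s <- quiet_sim(duration = 5, f = 4, fs = 200)
  cy <- s$truth$cycles
  d <- s$config$downstroke_fraction
  for (k in c(2, 10, 18)) {
    i <- which(s$accel$time >= cy$start_time[k] & s$accel$time < cy$end_time[k])
    tpk <- s$accel$time[i][which.max(s$accel$z[i])]
    expect_lt(abs(tpk - (cy$start_time[k] + d / 2 * cy$period[k])), 1 / 200 + 1e-12)
  }

  # peak-to-peak heave equals gain * range of the wing angular velocity,
  # checked against a numerical-derivative oracle of the elevation waveform
  cfg <- sim_config(duration = 2, accel_rate = 2000, wingbeat_frequency = 5,
                    wing_amplitude = 90, track_segments = list(
                      list(mode = "level", v_z = 0, groundspeed = c(10, 0),
                           duration = 2)))
  s2 <- simulate_flight(cfg)
  m <- simulate_wing_motion(cfg, rate = 2000)
  omega_num <- num_deriv(m$samples$time, m$samples$elevation * pi / 180)
  pp_oracle <- cfg$heave_gain * diff(range(omega_num))
  pp_sim <- diff(range(s2$accel$z))
  expect_equal(pp_sim, pp_oracle, tolerance = 1e-3)
  # symmetric-stroke closed form: gain * A_rad/2 * 2*pi*f gives the amplitude
  expect_equal(pp_sim, cfg$heave_gain * (90 * pi / 180 / 2) * 2 * pi * 5 * 2,
               tolerance = 1e-4)
})

test_that("magnetometer follows the dipole-plus-earth-field model", {
  # no magnet -> vector sum constant at |earth field|
  s <- quiet_sim(duration = 2, magnet_moment = 0)
  vs <- mag_vector_sum(s$mag)
  expect_equal(vs, rep(sqrt(sum(s$config$earth_field^2)), length(vs)))

  # inverse-cube law: dipole magnitude at 2r is 1/8 of that at r
  cfg <- sim_config()
  r <- 0.05
  expect_equal((cfg$magnet_moment / (2 * r)^3) / (cfg$magnet_moment / r^3), 1 / 8)

  # noiseless: per-cycle vector-sum maximum at the sample nearest downstroke start
  s2 <- quiet_sim(duration = 5, f = 4, fs = 200)
  cy <- s2$truth$cycles
  vs2 <- mag_vector_sum(s2$mag)
  for (k in c(3, 9, 15)) {
    i <- which(s2$mag$time >= cy$start_time[k] & s2$mag$time < cy$end_time[k])
    tpk <- s2$mag$time[i][which.max(vs2[i])]
    off <- min(abs(tpk - cy$start_time[k]), abs(tpk - cy$end_time[k]))
    expect_lt(off, 1 / 200 + 1e-12)
  }
})

test_that("increasing wing amplitude increases heave and magnetometer peaks", {
  amps <- c(40, 60, 80, 100, 120)
  pp <- sapply(amps, function(A) {
    s <- quiet_sim(duration = 2, wing_amplitude = A)
    diff(range(s$accel$z))
  })
  mx <- sapply(amps, function(A) {
    s <- quiet_sim(duration = 2, wing_amplitude = A)
    max(mag_vector_sum(s$mag))
  })
  expect_true(all(diff(pp) > 0))
  expect_true(all(diff(mx) > 0))
})

test_that("identical config and seed give bit-identical traces", {
  cfg <- sim_config(duration = 3, noise_sd = c(accel = 0.1, mag = 0.5), seed = 77)
  s1 <- simulate_flight(cfg)
  s2 <- simulate_flight(cfg)
  expect_identical(s1$accel, s2$accel)
  expect_identical(s1$mag, s2$mag)
  expect_identical(s1$pressure, s2$pressure)
})

test_that("estimated heave amplitude is insensitive to the sampling rate", {
  for (f in c(2, 5, 8)) {
    amp <- sapply(c(40, 180), function(fs) {
      s <- simulate_flight(sim_config(duration = 20, accel_rate = fs,
                                      wingbeat_frequency = f, seed = 21))
      w <- wingbeats(s$accel, suggest_detection_params(fs, f))
      mean(w$cycles$heave_amplitude)
    })
    expect_lt(abs(amp[1] - amp[2]) / amp[2], 0.05)
  }
})

test_that("track simulation integrates segments and round-trips pressure", {
  # single level segment: V_z = 0, pressure constant
  s <- quiet_sim(duration = 4)
  expect_equal(s$truth$state$v_z, rep(0, nrow(s$truth$state)))
  expect_equal(diff(range(s$pressure$pa)), 0)

  # climb 1 m/s for 60 s -> 60 m; pressure inverts to the same altitude
  cfg <- sim_config(duration = 60, track_segments = list(
    list(mode = "climb", v_z = 1, groundspeed = c(10, 0), duration = 60)))
  tr <- simulate_track(cfg)
  expect_equal(tr$truth$altitude[nrow(tr$truth)], 60, tolerance = 1e-9)
  expect_equal(barometric_altitude(tr$pressure$pa[nrow(tr$pressure)]),
               60, tolerance = 1e-9)

  # zero wind: airspeed equals groundspeed magnitude at every sample
  expect_equal(tr$truth$airspeed, rep(10, nrow(tr$truth)))

  # overlapping / non-tiling segments rejected
  expect_error(sim_config(duration = 10, track_segments = list(
    list(mode = "level", v_z = 0, groundspeed = c(10, 0), duration = 7),
    list(mode = "climb", v_z = 1, groundspeed = c(10, 0), duration = 7))),
    "tile")
})

test_that("noiseless detection recovers every flapping cycle (round trip)", {
  s <- simulate_flight(sim_config(duration = 20,
                                  glide_bouts = list(c(5, 8), c(12.3, 14.8)),
                                  seed = 5))
  w <- wingbeats(s$accel, suggest_detection_params(100, 5))
  n_true <- nrow(s$truth$cycles)
  n_bouts <- 3L # flapping bouts delimited by the two glides
  expect_identical(length(w$peaks), n_true)
  # peak-to-peak segmentation yields one cycle fewer per flapping bout
  expect_identical(nrow(w$cycles), n_true - n_bouts)
  expect_lt(max(abs(w$cycles$frequency - 5)) , 5 * 0.02)
})

test_that("simulation writes value-identical CSV streams", {
  dir <- withr::local_tempdir()
  s <- quiet_sim(duration = 2)
  write_simulation(s, dir)
  expect_setequal(list.files(dir),
                  c("accel.csv", "mag.csv", "track.csv", "pressure.csv",
                    "wind.csv", "ground_truth.json"))
  a <- read_trace(file.path(dir, "accel.csv"),
                  columns = c(time = "time", x = "ax", y = "ay", z = "az"))
  expect_equal(a$z, s$accel$z, tolerance = 1e-12)
})
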