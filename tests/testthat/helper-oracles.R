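# Independent oracles used across tests; deliberately brute-force and kept
# separate from the implementation paths they check.

# Exhaustive local-maximum oracle: a strict rise followed (possibly across a
# plateau) by a fall; the peak index is the first plateau sample. Terminal
# plateaus are not maxima.
local_max_oracle <- function(x) {
  n <- length(x)
  out <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Numerical derivative of a sampled waveform (central differences).
num_deriv <- function(t, x) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  d
}

# Closed-form OLS via the normal equations.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# A default noiseless simulation used by several tests.
quiet_sim <- function(duration = 10, f = 5, fs = 100, ...) {
  simulate_flight(sim_config(duration = duration, accel_rate = fs,
                             mag_rate = fs, wingbeat_frequency = f, ...))
}
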