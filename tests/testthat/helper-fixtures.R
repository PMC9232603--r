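# Shared fixtures, all generated in code.

# Noiseless, jitter-free default session (no EMG unless asked): the
# programmed profile is then exactly recoverable.
noiseless_params <- function(variant = "DL-EV", muscles = NULL, ...) {
  synthesis_params(variant = variant,
                   duration_jitter_cv = 0,
                   noise_sd = list(pitch = 0, roll = 0, accel = 0,
                                   force = 0, cop = 0),
                   muscles = muscles, include_gridcop = FALSE, ...)
}

# Piecewise-linear trapezoid pitch trace with analytic corner times.
linear_trapezoid_trace <- function(r0, rise, hold, drop, peak = 25,
                                   rate = 30, lead = 3, tail = 3) {
  r1 <- r0 + rise; r2 <- r1 + hold; r3 <- r2 + drop
  t <- seq(0, r3 + tail, by = 1 / rate)
  up <- peak * pmin(pmax((t - r0) / rise, 0), 1)
  dn <- peak * pmin(pmax((t - r2) / drop, 0), 1)
  structure(data.frame(time = t, pitch = up - dn),
            class = c("pitch_trace", "data.frame"),
            corners = c(r0, r1, r2, r3))
}

random_insole_stream <- function(n = 20, rate = 30) {
  t <- (seq_len(n) - 1) / rate
  insole_stream(t,
                F1 = runif(n, 0, 50), F2 = runif(n, 0, 300),
                F3 = runif(n, 0, 300), F4 = runif(n, 0, 400),
                ax = rnorm(n, 0, 0.1), ay = rnorm(n, 0, 0.1),
                az = rnorm(n, 1, 0.1), rate_hz = rate)
}

# Brute-force waveform-length oracle, straight from the definition.
wl_oracle <- function(x, N) {
  out <- rep(NA_real_, length(x))
  for (t in N:length(x)) {
    acc <- 0
    for (n in (t - N + 2):t) acc <- acc + abs(x[n] - x[n - 1])
    out[t] <- acc
  }
  out
}
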