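# Shared fixtures, built in code.

# narrowband pair with y a circularly delayed copy of x plus independent
# noise; positive lag_s means x leads y
lagged_pair <- function(n_s = 60, fs = 1000, band = c(8, 12), lag_s = 0.025,
                        noise_sd = sqrt(0.1), seed = 1) {
  set.seed(seed)
  n <- n_s * fs
  b <- neurodyn:::narrowband_noise(n, fs, band[1], band[2])
  lag <- round(lag_s * fs)
  y_base <- if (lag > 0) c(b[(n - lag + 1):n], b[seq_len(n - lag)]) else b
  list(x = b + noise_sd * rnorm(n),
       y = y_base + noise_sd * rnorm(n),
       fs = fs, n = n)
}

# amplitude-modulated carrier coupled to a stochastic slow rhythm
# (narrowband noise, so circular shifts genuinely decouple the pair)
pac_signal <- function(n_s = 60, fs = 1000, f_phase = 8, f_amp = 80,
                       kappa = 0.9, noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  t <- seq(0, n_s - 1 / fs, by = 1 / fs)
  n <- length(t)
  slow <- neurodyn:::narrowband_noise(n, fs, f_phase - 1, f_phase + 1)
  phi <- Arg(neurodyn:::analytic_signal(slow))
  env <- (1 + kappa * cos(phi)) / (1 + kappa)
  x <- slow + env * cos(2 * pi * f_amp * t) + noise_sd * rnorm(n)
  list(x = x, t = t, env = env, fs = fs)
}

unwrap_phase <- function(p) {
  jumps <- c(0, diff(p))
  p + 2 * pi * cumsum((jumps < -pi) - (jumps > pi))
}

quick_session <- function(duration_s = 60, condition = "healthy_saline",
                          seed = 1, ...) {
  gen_lfp_session(session_config(duration_s = duration_s,
                                 condition = condition,
                                 injection_s = 0, seed = seed, ...))
}
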