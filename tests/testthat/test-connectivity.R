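test_that("wPLI separates lagged coupling from zero-lag leakage", {
  pr <- lagged_pair(60, band = c(8, 12), lag_s = 0.025, seed = 1)
  expect_gt(wpli(pr$x, pr$y, pr$fs, c(8, 12)), 0.9)

  set.seed(2)
  x <- pr$x
  y0 <- 0.5 * x + 0.001 * rnorm(length(x))
  expect_lt(wpli(x, y0, pr$fs, c(8, 12)), 0.1)

  expect_error(wpli(c(x, NA), c(pr$y, 1), pr$fs, c(8, 12)), "NA|NaN")
})

test_that("wPLI is bounded and scale invariant", {
  pr <- lagged_pair(30, seed = 3)
  w <- wpli(pr$x, pr$y, pr$fs, c(8, 12))
  expect_gte(w, 0)
  expect_lte(w, 1)
  expect_equal(wpli(5 * pr$x, 0.2 * pr$y, pr$fs, c(8, 12)), w,
               tolerance = 1e-6)
})

test_that("independent noise stays inside its own time-shift null", {
  set.seed(4)
  fs <- 250
  x <- rnorm(60 * fs)
  y <- rnorm(60 * fs)
  obs <- wpli(x, y, fs, c(8, 12))
  set.seed(5)
  null <- surrogate_null(function(a, b) wpli(a, b, fs, c(8, 12)),
                         x, y, fs, n = 19)
  expect_lt(obs, null$quantiles[["95%"]] * 1.5)
})

test_that("a common zero-lag source barely moves wPLI but inflates coherence", {
  d_wpli <- coh_gain <- wpli_indep <- numeric(20)
  for (s in 1:20) {
    pr <- lagged_pair(30, band = c(8, 12), lag_s = 0.025,
                      noise_sd = 1, seed = 200 + s)
    set.seed(300 + s)
    common <- neurodyn:::pink_noise(pr$n, 1, 1)
    # broadband unit-gain common source: lagged-pair theta wPLI barely moves
    d_wpli[s] <- wpli(pr$x + common, pr$y + common, pr$fs, c(8, 12)) -
      wpli(pr$x, pr$y, pr$fs, c(8, 12))
    # theta-band common source on an independent pair: ordinary coherence
    # inflates, wPLI does not follow
    u <- rnorm(pr$n)
    v <- rnorm(pr$n)
    theta_common <- neurodyn:::narrowband_noise(pr$n, pr$fs, 8, 12)
    coh_gain[s] <- band_coherence(u + theta_common, v + theta_common,
                                  pr$fs, c(8, 12)) -
      band_coherence(u, v, pr$fs, c(8, 12))
    wpli_indep[s] <- wpli(u + theta_common, v + theta_common, pr$fs, c(8, 12))
  }
  expect_lt(max(abs(d_wpli)), 0.15)
  expect_gt(mean(coh_gain), 0.3)
  expect_lt(mean(wpli_indep), 0.2)
})

test_that("wPLI spectrogram is band-selective with stable windows", {
  pr <- lagged_pair(300, fs = 250, band = c(8, 12), lag_s = 0.025, seed = 6)
  tr <- wpli_spectrogram(pr$x, pr$y, pr$fs, freq_range = c(4, 80),
                         step = 4, window_s = 60)
  expect_length(tr$times, 5)
  td <- tidy(tr)
  theta <- td$value[td$freq > 8 & td$freq < 12]
  gamma <- td$value[td$freq > 60 & td$freq < 80]
  expect_gt(mean(theta), 3 * mean(gamma))
  expect_lt(sd(theta) / mean(theta), 0.5)
})

test_that("PSI is exactly antisymmetric and sign-codes the leader", {
  pr <- lagged_pair(120, band = c(4, 10), lag_s = 0.020,
                    noise_sd = 0.3, seed = 7)
  p_xy <- psi(pr$x, pr$y, pr$fs, c(4, 10))
  p_yx <- psi(pr$y, pr$x, pr$fs, c(4, 10))
  expect_identical(p_xy, -p_yx)
  expect_gt(p_xy, 0)  # x leads

  signs <- vapply(1:20, function(s) {
    pr <- lagged_pair(60, band = c(4, 10), lag_s = 0.020,
                      noise_sd = 0.3, seed = 400 + s)
    sign(psi(pr$x, pr$y, pr$fs, c(4, 10)))
  }, numeric(1))
  expect_gte(mean(signs > 0), 0.95)

  expect_error(psi(pr$x, pr$y, pr$fs, c(4, 4.5)), "narrower")
})

test_that("independent noise PSI sits inside its surrogate null band", {
  set.seed(8)
  fs <- 250
  x <- rnorm(120 * fs)
  y <- rnorm(120 * fs)
  obs <- psi(x, y, fs, c(4, 10))
  set.seed(9)
  null <- surrogate_null(function(a, b) psi(a, b, fs, c(4, 10)),
                         x, y, fs, n = 39)
  expect_gt(obs, null$quantiles[["2.5%"]])
  expect_lt(obs, null$quantiles[["97.5%"]])
})

test_that("PSI spectrogram negates exactly under channel swap", {
  pr <- lagged_pair(120, fs = 250, band = c(4, 10), lag_s = 0.02, seed = 10)
  t1 <- psi_spectrogram(pr$x, pr$y, pr$fs, freq_range = c(2, 20),
                        step = 2, window_s = 60)
  t2 <- psi_spectrogram(pr$y, pr$x, pr$fs, freq_range = c(2, 20),
                        step = 2, window_s = 60)
  expect_identical(t1$values, -t2$values)
  expect_length(t1$times, 2)
  theta_cols <- t1$freqs >= 4 & t1$freqs <= 10
  expect_gte(mean(sign(t1$values[, theta_cols]) > 0), 0.9)
})

test_that("surrogate generator validates its arguments", {
  expect_error(surrogate_null(function(a, b) 0, rnorm(100), rnorm(100),
                              fs = 10, n = 0), "positive count")
  set.seed(1)
  x <- rnorm(3000)
  nn <- surrogate_null(function(a, b) cor(a, b), x, x, fs = 100, n = 19)
  expect_length(nn$values, 19)
  expect_true(all(abs(nn$values) < 0.9))  # shifts decorrelate
})
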