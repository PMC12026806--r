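test_that("multitaper PSD localizes a sine within the concentration band", {
  fs <- 1000
  x <- sin(2 * pi * 10 * seq(0, 60 - 1 / fs, by = 1 / fs))
  psd <- multitaper_psd(x, fs, nw = 5, k = 9)
  peak <- psd$freq[which.max(psd$power)]
  expect_lt(abs(peak - 10), 5 / 60)  # NW / T half-bandwidth
  expect_true(all(psd$power >= 0))
  expect_true(all(multitaper_psd(numeric(2000), fs)$power == 0))
})

test_that("multitaper PSD of white noise is flat and variance-reduced", {
  fs <- 500
  mean_psd <- NULL
  for (s in 1:20) {
    set.seed(s)
    psd <- multitaper_psd(rnorm(10 * fs), fs)
    mean_psd <- if (is.null(mean_psd)) psd$power else mean_psd + psd$power
  }
  bands <- cut(psd$freq, seq(2, 200, by = 22))
  m <- tapply(mean_psd / 20, bands, mean)
  expect_lt(max(m, na.rm = TRUE) / min(m, na.rm = TRUE), 1.2)

  # K = 9 tapers beat a single taper in estimator variance
  v9 <- v1 <- numeric(20)
  for (s in 1:20) {
    set.seed(100 + s)
    x <- rnorm(4 * fs)
    sel <- function(p) p$power[p$freq > 10 & p$freq < 200]
    v9[s] <- var(sel(multitaper_psd(x, fs, nw = 5, k = 9)))
    v1[s] <- var(sel(multitaper_psd(x, fs, nw = 5, k = 1)))
  }
  expect_lt(mean(v9), mean(v1))
})

test_that("PSD integrates to the signal variance (Parseval)", {
  set.seed(3)
  fs <- 1000
  x <- rnorm(30 * fs)
  psd <- multitaper_psd(x, fs)
  total <- sum(psd$power) * fs / length(x)
  expect_lt(abs(total / var(x) - 1), 0.1)
})

test_that("spectrogram windowing and power scaling behave", {
  set.seed(4)
  fs <- 200
  x <- rnorm(600 * fs)
  sp <- mt_spectrogram(x, fs, window_s = 60)
  expect_length(sp$times, 10)

  bp <- band_power(sp, c(10, 40))
  expect_lt(sd(bp$power) / mean(bp$power), 0.3)

  # amplitude step x2 at midpoint -> 4x band power
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  amp <- ifelse(t < 300, 1, 2)
  y <- amp * sin(2 * pi * 3 * t) + 0.01 * rnorm(length(t))
  spy <- mt_spectrogram(y, fs, window_s = 60)
  d <- band_power(spy, "delta")
  ratio <- mean(d$power[6:10]) / mean(d$power[1:5])
  expect_lt(abs(ratio - 4), 0.4)

  # c^2 scale equivariance, exact
  sp2 <- mt_spectrogram(3 * x, fs, window_s = 60)
  expect_equal(sp2$power, 9 * sp$power, tolerance = 1e-12)
})

test_that("1/f normalization flattens a 1/f spectrum and drops f = 0", {
  sp <- structure(list(
    times = c(30, 90),
    freqs = seq(0, 100, by = 0.5),
    power = matrix(rep(c(Inf, 1 / seq(0.5, 100, by = 0.5)), each = 2), nrow = 2),
    norm_state = "raw", window_s = 60, taper_params = c(nw = 5, k = 9)
  ), class = "spectrogram")
  sp$power[, 1] <- 10  # arbitrary finite DC
  out <- one_over_f_normalize(sp)
  expect_false(0 %in% out$freqs)
  expect_equal(as.vector(out$power), rep(1, length(out$freqs) * 2))
  expect_error(one_over_f_normalize(out), "already")

  # white noise -> linear in f
  spw <- sp
  spw$power <- matrix(1, nrow = 2, ncol = length(sp$freqs))
  outw <- one_over_f_normalize(spw)
  expect_equal(as.vector(outw$power[1, ]), outw$freqs)
})

test_that("band power separates planted bands", {
  fs <- 1000
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  x3 <- sin(2 * pi * 3 * t)
  sp <- mt_spectrogram(x3, fs, window_s = 60)
  expect_gt(mean(band_power(sp, "delta")$power) /
            mean(band_power(sp, "theta")$power), 100)

  y <- sin(2 * pi * 10 * t) + sin(2 * pi * 40 * t)
  spy <- mt_spectrogram(y, fs, window_s = 60)
  th <- mean(band_power(spy, c(8, 12))$power)
  lg <- mean(band_power(spy, c(38, 42))$power)
  expect_lt(abs(th / lg - 1), 0.05)

  expect_error(band_power(sp, c(600, 700)), "no frequency bins")
})

test_that("baseline z-scoring has the defining fixed points", {
  x <- c(1, 2, 3, 4, 10, 12)
  z <- zscore_to_baseline(x, 1:4)
  expect_equal(mean(z[1:4]), 0)
  expect_equal(sd(z[1:4]), 1)

  b <- c(5, 6, 7)
  z2 <- zscore_to_baseline(c(b, mean(b) + 2 * sd(b)), 1:3)
  expect_equal(z2[4], 2)

  # invariance to common scaling
  expect_equal(zscore_to_baseline(10 * x, 1:4), z)
  expect_error(zscore_to_baseline(c(1, 1, 2), 1:2), "variance")
  expect_error(zscore_to_baseline(x, 2), "at least 2")
})
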