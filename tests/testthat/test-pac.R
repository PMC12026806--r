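test_that("phase and amplitude extraction recover planted structure", {
  fs <- 1000
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 8 * t)
  pa <- extract_phase_amp(x, fs, phase_band = c(6, 10))
  core <- 2000:28000
  slope <- coef(lm(unwrap_phase(pa$phase[core]) ~ t[core]))[2]
  expect_lt(abs(slope / (2 * pi * 8) - 1), 0.001)

  carrier <- cos(2 * pi * 80 * t)
  am <- extract_phase_amp(carrier, fs, amp_band = c(75, 85))$amplitude
  expect_lt(sd(am[core]) / mean(am[core]), 0.02)

  sig <- pac_signal(30, fs, kappa = 0.6, noise_sd = 0)
  am2 <- extract_phase_amp(sig$x, fs, amp_band = c(75, 85))$amplitude
  expect_gt(cor(am2[core], sig$env[core]), 0.95)
})

test_that("modulation index matches closed-form distributions", {
  n <- 18 * 500
  phase <- rep(seq(-pi + pi / 18, pi - pi / 18, length.out = 18), times = 500)

  # uniform amplitude -> MI = 0
  expect_equal(modulation_index(phase, rep(2.5, n)), 0)

  # all mass in one bin -> MI = 1 (with empty-bin fallback flagged)
  amp1 <- as.numeric(abs(phase - phase[1]) < 1e-12)
  mi1 <- modulation_index(phase[amp1 == 1], amp1[amp1 == 1])
  expect_equal(as.numeric(mi1), 1, tolerance = 1e-9)
  expect_false(is.null(attr(mi1, "empty_bins")))

  # mixture: one bin holds 0.5, the other 17 hold 0.5/17 each
  amp <- ifelse(abs(phase - phase[1]) < 1e-12, 0.5, 0.5 / 17)
  mi <- as.numeric(modulation_index(phase, amp))
  p <- c(0.5, rep(0.5 / 17, 17))           # independent evaluation
  h <- -sum(p * log(p))
  expect_equal(mi, (log(18) - h) / log(18), tolerance = 1e-9)
  expect_equal(mi, 0.2700753, tolerance = 1e-6)
})

test_that("MI is bounded and exactly amplitude-scale invariant", {
  set.seed(7)
  for (i in 1:10) {
    phase <- runif(2000, -pi, pi)
    amp <- abs(rnorm(2000)) * exp(cos(phase))
    mi <- as.numeric(modulation_index(phase, amp))
    expect_gte(mi, 0)
    expect_lte(mi, 1)
    expect_equal(mi, as.numeric(modulation_index(phase, amp * 17.3)),
                 tolerance = 1e-12)
  }
})

test_that("comodulogram finds planted coupling at the right cell", {
  sig <- pac_signal(120, 1000, f_phase = 8, f_amp = 80, kappa = 0.9,
                    noise_sd = 0.3)
  grid <- pac_grid(phase_centers = seq(3, 15, by = 1),
                   amp_centers = seq(40, 120, by = 5))
  com <- comodulogram(sig$x, 1000, grid)
  peak <- which(com$mi == max(com$mi, na.rm = TRUE), arr.ind = TRUE)
  expect_lte(abs(com$phase_freqs[peak[1]] - 8), 2)
  expect_lte(abs(com$amp_freqs[peak[2]] - 80), 10)
  expect_true(all(com$mi >= 0 & com$mi <= 1, na.rm = TRUE))

  # sub-0.5 Hz phase bands are masked on the default grid
  full <- pac_grid()
  masks <- neurodyn:::grid_masks(full, 1000)
  expect_equal(full$phase_centers[!masks$phase], c(0, 1, 2))
})

test_that("ROI coupling grows monotonically with planted strength", {
  kappas <- seq(0, 0.9, by = 0.1)
  roi <- list(phase_lo = 6, phase_hi = 10, amp_lo = 70, amp_hi = 90)
  grid <- pac_grid(phase_centers = 8, amp_centers = 80, window_s = 30)
  mi_mean <- vapply(kappas, function(k) {
    mean(vapply(1:5, function(s) {
      sig <- pac_signal(30, 1000, kappa = k, noise_sd = 0.3, seed = s)
      pac_roi_series(sig$x, 1000, roi, grid)$mi[1]
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(kappas, mi_mean, method = "spearman"), 0.95)
})

test_that("roi_mean averages the intended cells", {
  com <- structure(list(phase_freqs = 3:10, amp_freqs = seq(20, 100, 10),
                        mi = matrix(0.25, 8, 9), n_bins = 18),
                   class = "comodulogram")
  expect_equal(roi_mean(com, list(phase_lo = 4, phase_hi = 8,
                                  amp_lo = 30, amp_hi = 70)), 0.25)
  com$mi[3, 4] <- 0.9
  expect_equal(roi_mean(com, list(phase_lo = 5, phase_hi = 5,
                                  amp_lo = 50, amp_hi = 50)), 0.9)
  expect_error(roi_mean(com, list(phase_lo = 20, phase_hi = 25,
                                  amp_lo = 30, amp_hi = 70)), "intersect")
})

test_that("circular shifts destroy planted coupling", {
  sig <- pac_signal(60, 1000, kappa = 0.9, noise_sd = 0.3, seed = 2)
  roi <- list(phase_lo = 6, phase_hi = 10, amp_lo = 70, amp_hi = 90)
  grid <- pac_grid(phase_centers = 8, amp_centers = 80, window_s = 60)
  obs <- pac_roi_series(sig$x, 1000, roi, grid)$mi[1]
  set.seed(1)
  null <- pac_surrogate_null(sig$x, 1000, roi, grid, n = 19)
  expect_gt(obs, quantile(null, 0.95))
  expect_lt(mean(null) / obs, 0.2)
})
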