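test_that("session generation is a pure function of config and seed", {
  cfg <- session_config(duration_s = 10, seed = 42)
  r1 <- gen_lfp_session(cfg)
  r2 <- gen_lfp_session(cfg)
  expect_identical(r1$lfp, r2$lfp)
  expect_identical(r1$acc, r2$acc)
  r3 <- gen_lfp_session(session_config(duration_s = 10, seed = 43))
  expect_false(identical(r1$lfp, r3$lfp))
})

test_that("config validation rejects impossible sessions", {
  expect_error(session_config(duration_s = 0), "positive")
  expect_error(session_config(fs_raw = 1500, fs_lfp = 1000), "fs_lfp")
  expect_error(session_config(pac_specs = list(list(phase_freq = 8,
    amp_freq = 80, kappa = 1.5))), "kappa")
  expect_error(session_config(duration_s = 10,
    interregion_lag_ms = 8000), "lag")
  expect_error(session_config(band_amplitudes = c(bogus = 1)), "power bands")
})

test_that("1/f background has the configured log-log slope", {
  slopes <- vapply(1:20, function(s) {
    set.seed(s)
    x <- neurodyn:::pink_noise(60000, alpha = 1)
    psd <- multitaper_psd(x, 1000, nw = 5, k = 9)
    sel <- psd$freq >= 1 & psd$freq <= 100
    unname(coef(lm(log(psd$power[sel]) ~ log(psd$freq[sel])))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-1)), 0.15)
})

test_that("condition power gain doubles delta band power", {
  ratios <- vapply(1:20, function(s) {
    sp <- quick_session(60, "spcp_saline", seed = s)
    he <- quick_session(60, "healthy_saline", seed = s)
    bp <- function(x) {
      p <- Mod(fft(x))^2
      f <- (seq_along(x) - 1) * 1000 / length(x)
      mean(p[f >= 2 & f <= 5])
    }
    bp(sp$lfp["CA1", ]) / bp(he$lfp["CA1", ])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2), 0.2)
})

test_that("uncoupled sessions show no ROI coupling beyond the shuffle null", {
  rec <- gen_lfp_session(session_config(duration_s = 120, injection_s = 0,
    pac_specs = list(list(phase_freq = 8, amp_freq = 75, kappa = 0,
                          channel = "CA1")), seed = 9))
  roi <- list(phase_lo = 5, phase_hi = 10, amp_lo = 50, amp_hi = 100)
  grid <- pac_grid(phase_centers = c(6, 8, 10), amp_centers = c(60, 75, 90))
  obs <- pac_roi_series(rec$lfp["CA1", ], 1000, roi, grid)
  set.seed(1)
  null <- pac_surrogate_null(rec$lfp["CA1", ], 1000, roi, grid, n = 19)
  expect_lt(mean(obs$mi), quantile(null, 0.95) * 2)
  expect_lt(mean(obs$mi) / mean(null), 3)  # indistinguishable scale
})

test_that("interregion lag plants recoverable directionality", {
  rec <- quick_session(120, seed = 5)
  p <- psi(rec$lfp["CA1", ], rec$lfp["PL", ], rec$fs, c(4, 10))
  expect_gt(p, 0)  # positive lag: CA1 leads
})

test_that("visit tables follow the planted novel-object preference", {
  v1 <- gen_visit_table(50, p_novel = 1, seed = 1)
  s1 <- exploration_summary(v1)
  expect_equal(s1$di, 1)

  v2 <- gen_visit_table(10000, p_novel = 0.5, seed = 2)
  s2 <- exploration_summary(v2)
  expect_lt(abs(s2$di), 0.05)

  expect_identical(gen_visit_table(20, 0.3, seed = 7),
                   gen_visit_table(20, 0.3, seed = 7))

  v0 <- gen_visit_table(0, 0.5)
  expect_equal(nrow(v0), 0)
  expect_true(attr(v0, "flagged"))
  expect_error(gen_visit_table(10, p_novel = 1.2), "probability")
})

test_that("count tables have binomial co-expression structure", {
  z <- gen_count_table(c(female = 2, male = 2), 3, marker_rate = 30,
                       coexpr_prob = 0, seed = 1)
  expect_true(all(z$n_coexpress == 0))

  big <- gen_count_table(c(female = 5, male = 4), 5, marker_rate = 200,
                         coexpr_prob = 0.5, seed = 2)
  pct <- 100 * sum(big$n_coexpress) / sum(big$n_marker_pos)
  expect_lt(abs(pct - 50), 3)

  expect_identical(gen_count_table(c(f = 2), 2, 10, 0.4, seed = 5),
                   gen_count_table(c(f = 2), 2, 10, 0.4, seed = 5))
  expect_true(all(big$n_coexpress <= big$n_marker_pos))
})
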