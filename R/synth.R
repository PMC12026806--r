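# Synthetic two-region LFP sessions with planted, recoverable structure:
# 1/f background, band-limited oscillations, phase-amplitude coupling,
# a lagged shared component between regions, an optional zero-lag common
# source, and an activity-modulated accelerometer.

CONDITIONS <- c("healthy_saline", "healthy_drug", "spcp_saline", "spcp_drug")

#' Condition effect presets
#'
#' Band-power multipliers (power gains applied to the planted oscillations
#' after the injection time), aberrant coupling strength and activity gain
#' for each experimental condition. The sPCP phenotype raises delta power,
#' lowers theta and low-gamma power, and adds delta-high-frequency coupling
#' in CA1 plus delta-high-gamma coupling in PL; the drug condition halves
#' each deviation from 1. Magnitudes are synthetic conventions (the study
#' reports directions and F statistics, not effect sizes).
#'
#' @param condition One of `"healthy_saline"`, `"healthy_drug"`,
#'   `"spcp_saline"`, `"spcp_drug"`.
#' @return A list with `multipliers` (named power gains), `pac_kappa`
#'   (aberrant-coupling strength) and `activity_gain`.
#' @export
condition_preset <- function(condition = CONDITIONS) {
  condition <- match.arg(condition)
  switch(condition,
    healthy_saline = list(
      multipliers = c(delta = 1, theta = 1, low_gamma = 1),
      pac_kappa = 0, activity_gain = 0.8
    ),
    healthy_drug = list(
      multipliers = c(delta = 1, theta = 1, low_gamma = 1),
      pac_kappa = 0, activity_gain = 0.8
    ),
    spcp_saline = list(
      multipliers = c(delta = 2.0, theta = 0.6, low_gamma = 0.6),
      pac_kappa = 0.5, activity_gain = 1.5
    ),
    spcp_drug = list(
      multipliers = c(delta = 1.5, theta = 0.8, low_gamma = 0.8),
      pac_kappa = 0.25, activity_gain = 0.8
    )
  )
}

#' Configure a synthetic recording session
#'
#' @param duration_s Session length in seconds.
#' @param fs_lfp LFP sampling rate in Hz (signals are synthesized at this
#'   rate; all planted content lies below 250 Hz).
#' @param fs_raw Nominal wideband acquisition rate in Hz; must be an integer
#'   multiple of at least `2 * fs_lfp`. Used when a wideband trace is
#'   requested (`synth_raw = TRUE`) to exercise the preprocessing chain.
#' @param band_amplitudes Named amplitudes (a.u.) of the planted band-limited
#'   oscillations; names must be power bands (see [band_set()]).
#' @param one_over_f_exponent Spectral exponent alpha of the 1/f^alpha
#'   background.
#' @param noise_sd Standard deviation of the 1/f background.
#' @param pac_specs List of coupling specs, each a list with `phase_freq`,
#'   `amp_freq` (Hz), `kappa` in \[0, 1\], optional `carrier_amp` (default
#'   0.5) and `channel` (`"CA1"`, `"PL"` or `"both"`, default `"both"`).
#' @param interregion_lag_ms Delay of the shared band-limited component in
#'   the PL channel relative to CA1 (positive lag = CA1 leads).
#' @param interregion_band Frequency band (Hz) of the shared component.
#' @param interregion_gain Amplitude (a.u.) of the shared component.
#' @param common_source_gain Amplitude of a zero-lag broadband source added
#'   identically to both channels (the nuisance wPLI must reject).
#' @param condition Experimental condition; selects [condition_preset()]
#'   effects unless `condition_multipliers` overrides them.
#' @param condition_multipliers Optional named power gains overriding the
#'   preset multipliers.
#' @param injection_s Time (s) at which condition effects ramp in; use 0 to
#'   apply them for the whole session.
#' @param synth_raw If `TRUE`, also synthesize a wideband trace at `fs_raw`
#'   (band-limited interpolation of the LFP plus white wideband noise).
#' @param seed Integer seed; the generated session is a pure function of the
#'   configuration including this seed.
#' @return A `session_config` list.
#' @export
session_config <- function(duration_s = 600,
                           fs_lfp = 1000,
                           fs_raw = 30000,
                           band_amplitudes = c(delta = 2, theta = 2,
                                               beta = 0.8, low_gamma = 0.8,
                                               high_gamma = 0.5),
                           one_over_f_exponent = 1,
                           noise_sd = 1,
                           pac_specs = list(list(phase_freq = 8,
                                                 amp_freq = 75,
                                                 kappa = 0.4,
                                                 channel = "CA1")),
                           interregion_lag_ms = 20,
                           interregion_band = c(4, 10),
                           interregion_gain = 1,
                           common_source_gain = 0,
                           condition = "healthy_saline",
                           condition_multipliers = NULL,
                           injection_s = 900,
                           synth_raw = FALSE,
                           seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be positive")
  }
  if (fs_raw < 2 * fs_lfp) abort("`fs_raw` must be at least 2 * fs_lfp")
  if (fs_raw %% fs_lfp != 0) abort("`fs_raw` must be a multiple of `fs_lfp`")
  condition <- match.arg(condition, CONDITIONS)
  if (length(band_amplitudes) && (is.null(names(band_amplitudes)) ||
      any(!names(band_amplitudes) %in% band_set("power")$band))) {
    abort("`band_amplitudes` must be named with power bands")
  }
  if (any(band_amplitudes < 0)) abort("band amplitudes must be >= 0")
  for (ps in pac_specs) {
    if (is.null(ps$kappa) || ps$kappa < 0 || ps$kappa > 1) {
      abort("pac spec `kappa` must lie in [0, 1]")
    }
  }
  if (abs(interregion_lag_ms) / 1000 > duration_s / 2) {
    abort("inter-region lag exceeds half the session duration")
  }
  preset <- condition_preset(condition)
  mult <- preset$multipliers
  if (!is.null(condition_multipliers)) {
    mult[names(condition_multipliers)] <- condition_multipliers
  }
  if (any(mult <= 0)) abort("condition multipliers must be > 0")
  structure(list(
    duration_s = duration_s, fs_lfp = fs_lfp, fs_raw = fs_raw,
    band_amplitudes = band_amplitudes,
    one_over_f_exponent = one_over_f_exponent, noise_sd = noise_sd,
    pac_specs = pac_specs, interregion_lag_ms = interregion_lag_ms,
    interregion_band = interregion_band, interregion_gain = interregion_gain,
    common_source_gain = common_source_gain, condition = condition,
    condition_multipliers = mult, pac_kappa_condition = preset$pac_kappa,
    activity_gain = preset$activity_gain,
    injection_s = injection_s, synth_raw = synth_raw,
    seed = as.integer(seed)
  ), class = "session_config")
}

# 1/f^alpha background via spectral shaping of white Gaussian noise,
# normalized to unit standard deviation then scaled.
pink_noise <- function(n, alpha = 1, sd = 1) {
  w <- rnorm(n)
  W <- fft(w)
  f <- seq_len(n) - 1
  f[f > n / 2] <- n - f[f > n / 2]   # two-sided frequency index
  scale <- c(0, f[-1]^(-alpha / 2))  # drop DC
  x <- Re(fft(W * scale, inverse = TRUE)) / n
  sd * x / stats::sd(x)
}

# unit-RMS narrowband Gaussian noise, synthesized in the frequency domain:
# complex Gaussian spectrum confined to the band with raised-cosine edges
# (10% of the bandwidth), single inverse FFT
narrowband_noise <- function(n, fs, lo, hi) {
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  edge <- max((hi - lo) * 0.1, fs / n)
  gain <- numeric(n)
  in_band <- half & freqs >= lo - edge & freqs <= hi + edge
  f <- freqs[in_band]
  g <- rep(1, length(f))
  g[f < lo] <- 0.5 * (1 + cos(pi * (lo - f[f < lo]) / edge))
  g[f > hi] <- 0.5 * (1 + cos(pi * (f[f > hi] - hi) / edge))
  gain[in_band] <- g
  idx <- which(gain > 0)
  spec <- complex(length.out = n)
  spec[idx] <- complex(real = rnorm(length(idx)),
                       imaginary = rnorm(length(idx))) * gain[idx]
  # Hermitian mirror for a real signal
  mirror <- n - idx + 2
  keep <- mirror >= 1 & mirror <= n & mirror != idx
  spec[mirror[keep]] <- Conj(spec[idx[keep]])
  x <- Re(fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

# logistic ramp from 0 to 1 around the injection time (width ~ 10 s)
condition_ramp <- function(t, injection_s) {
  if (injection_s <= 0) return(rep(1, length(t)))
  1 / (1 + exp(-(t - injection_s - 15) / 5))
}

#' Generate a synthetic two-region LFP session
#'
#' Produces a deterministic recording given the configuration: CA1 and PL
#' channels share a band-limited component delayed in PL by
#' `interregion_lag_ms` (positive lag = CA1 leads); planted coupling
#' modulates a fast carrier by `(1 + kappa * cos(phi)) / (1 + kappa)` where
#' `phi` is the phase of the slow rhythm, so the mean carrier amplitude is
#' kappa-invariant; condition multipliers scale oscillation power from
#' `injection_s` onward; accelerometer channels carry an activity envelope
#' independent of the LFP noise.
#'
#' @param cfg A [session_config()].
#' @return An `lfp_recording`: list with `lfp` (2 x n matrix, rows CA1/PL),
#'   `acc` (3 x n), `fs`, `channel_labels`, `epoch_marks`, `config`, and
#'   optionally `raw`/`fs_raw`.
#' @export
gen_lfp_session <- function(cfg) {
  stopifnot(inherits(cfg, "session_config"))
  set.seed(cfg$seed)
  fs <- cfg$fs_lfp
  n <- round(cfg$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  ramp <- condition_ramp(t, cfg$injection_s)
  bands <- band_set("power")

  channels <- c("CA1", "PL")
  lfp <- matrix(0, nrow = 2, ncol = n, dimnames = list(channels, NULL))
  band_components <- list(CA1 = list(), PL = list())

  for (ch in channels) {
    sig <- pink_noise(n, cfg$one_over_f_exponent, cfg$noise_sd)
    for (b in names(cfg$band_amplitudes)) {
      lim <- band_limits(b)
      osc <- narrowband_noise(n, fs, lim[1], lim[2])
      gain <- cfg$condition_multipliers[b]
      g_t <- if (!is.na(gain) && gain != 1) {
        1 + (sqrt(gain) - 1) * ramp
      } else rep(1, n)
      amp <- cfg$band_amplitudes[[b]] / sqrt(2)
      band_components[[ch]][[b]] <- osc
      sig <- sig + amp * g_t * osc
    }
    lfp[ch, ] <- sig
  }

  # planted phase-amplitude coupling
  all_pac <- cfg$pac_specs
  if (cfg$pac_kappa_condition > 0) {
    # aberrant couplings emerging after injection: CA1 delta-HF, PL delta-HG
    all_pac <- c(all_pac, list(
      list(phase_freq = 3.5, amp_freq = 175, kappa = cfg$pac_kappa_condition,
           channel = "CA1", ramped = TRUE),
      list(phase_freq = 3.5, amp_freq = 90, kappa = cfg$pac_kappa_condition,
           channel = "PL", ramped = TRUE)
    ))
  }
  for (ps in all_pac) {
    chs <- if (is.null(ps$channel) || ps$channel == "both") channels else ps$channel
    c_amp <- ps$carrier_amp %||% 0.5
    for (ch in chs) {
      # phase driver: the planted oscillation of the band containing
      # phase_freq if one exists, else a dedicated slow narrowband
      host <- bands$band[bands$lo <= ps$phase_freq & bands$hi >= ps$phase_freq]
      host <- intersect(host, names(band_components[[ch]]))
      if (length(host)) {
        driver <- band_components[[ch]][[host[1]]]
      } else {
        # no band oscillation covers this phase frequency: plant a dedicated
        # slow rhythm and make it part of the trace
        driver <- narrowband_noise(n, fs, max(0.5, ps$phase_freq - 1),
                                   ps$phase_freq + 1)
        lfp[ch, ] <- lfp[ch, ] + (ps$driver_amp %||% 1) * driver
      }
      phi <- Arg(analytic_signal(driver))
      kap <- if (isTRUE(ps$ramped)) ps$kappa * ramp else rep(ps$kappa, n)
      env <- (1 + kap * cos(phi)) / (1 + kap)
      carrier <- cos(2 * pi * ps$amp_freq * t + runif(1, 0, 2 * pi))
      lfp[ch, ] <- lfp[ch, ] + c_amp * env * carrier
    }
  }

  # lagged shared component (CA1 leads PL for positive lag)
  if (cfg$interregion_gain > 0) {
    s <- narrowband_noise(n, fs, cfg$interregion_band[1], cfg$interregion_band[2])
    lag_smp <- round(cfg$interregion_lag_ms / 1000 * fs)
    s_pl <- if (lag_smp >= 0) {
      c(s[(n - lag_smp + 1):n], s[seq_len(n - lag_smp)])
    } else {
      c(s[(-lag_smp + 1):n], s[seq_len(-lag_smp)])
    }
    if (lag_smp == 0) s_pl <- s
    lfp["CA1", ] <- lfp["CA1", ] + cfg$interregion_gain * s
    lfp["PL", ] <- lfp["PL", ] + cfg$interregion_gain * s_pl
  }

  # zero-lag common source, added identically to both channels post-lag
  if (cfg$common_source_gain > 0) {
    common <- pink_noise(n, cfg$one_over_f_exponent, 1)
    lfp["CA1", ] <- lfp["CA1", ] + cfg$common_source_gain * common
    lfp["PL", ] <- lfp["PL", ] + cfg$common_source_gain * common
  }

  # accelerometer: shared slow activity envelope (smoothed rectified
  # Gaussian) times independent per-axis noise; activity changes with the
  # condition after injection
  env_raw <- abs(rnorm(n))
  k <- max(3, round(2 * fs))                       # ~2 s smoothing
  cs <- cumsum(c(env_raw, env_raw[seq_len(min(k, n))]))  # wrapped tail
  act <- (cs[seq_len(n) + min(k, n)] - cs[seq_len(n)]) / min(k, n)
  act <- act / mean(act)
  act <- act * (1 + (cfg$activity_gain - 1) * ramp)
  acc <- matrix(0, nrow = 3, ncol = n,
                dimnames = list(c("x", "y", "z"), NULL))
  for (a in 1:3) acc[a, ] <- act * rnorm(n)

  inj <- min(cfg$injection_s, cfg$duration_s)
  epochs <- if (inj > 0 && inj < cfg$duration_s) {
    list(baseline = c(0, inj), post = c(inj, cfg$duration_s))
  } else {
    list(session = c(0, cfg$duration_s))
  }

  rec <- structure(list(
    lfp = lfp, acc = acc, fs = fs, channel_labels = channels,
    epoch_marks = epochs, config = cfg
  ), class = "lfp_recording")

  if (isTRUE(cfg$synth_raw)) {
    q <- cfg$fs_raw / fs
    nr <- n * q
    raw <- matrix(0, nrow = 2, ncol = nr, dimnames = list(channels, NULL))
    for (ch in channels) {
      up <- stats::approx(seq_len(n), lfp[ch, ], n = nr)$y
      raw[ch, ] <- up + 0.05 * rnorm(nr)
    }
    rec$raw <- raw
    rec$fs_raw <- cfg$fs_raw
  }
  rec
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$lfp), ncol(x$lfp), x$fs, ncol(x$lfp) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  cat("  epochs:", paste(sprintf("%s [%g, %g]", names(x$epoch_marks),
      vapply(x$epoch_marks, `[`, 0, 1), vapply(x$epoch_marks, `[`, 0, 2)),
      collapse = "; "), "\n")
  if (!is.null(x$config)) cat("  condition:", x$config$condition, "\n")
  invisible(x)
}
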