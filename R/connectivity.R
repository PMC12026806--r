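# Inter-regional phase coherence (weighted phase-lag index) and signal
# directionality (phase slope index), with circular-shift surrogate nulls.
# Sign convention: positive PSI means the first signal (dHPC/CA1 by
# convention) leads the second (mPFC/PL).

#' Weighted phase-lag index in a band
#'
#' Both signals are band-passed (zero-phase Butterworth, order 3 as in the
#' classic pipeline), the analytic cross-spectrum terms
#' `I_t = Im(X_t * Conj(Y_t))` formed, and
#' `wPLI = |mean(I_t)| / mean(|I_t|)` (0 when the denominator vanishes).
#' Weighting by the imaginary part rejects zero-lag common-source
#' contributions. The non-debiased estimator is used (`debias = TRUE`
#' switches to the debiased square estimator).
#'
#' @param x,y Numeric signals of equal length.
#' @param fs Sampling rate (Hz).
#' @param band `c(lo, hi)` in Hz.
#' @param order Butterworth order (default 3).
#' @param debias Use the debiased squared estimator (default `FALSE`).
#' @return Scalar in \[0, 1\].
#' @export
wpli <- function(x, y, fs, band, order = 3, debias = FALSE) {
  if (length(x) != length(y)) abort("signals must have equal length")
  if (anyNA(x) || anyNA(y)) abort("NaN/NA samples in input")
  zx <- analytic_signal(butter_bandpass(x, fs, band[1], band[2], order))
  zy <- analytic_signal(butter_bandpass(y, fs, band[1], band[2], order))
  imag_cs <- Im(zx * Conj(zy))
  wpli_from_imag(imag_cs, debias)
}

wpli_from_imag <- function(imag_cs, debias = FALSE) {
  denom <- mean(abs(imag_cs))
  if (denom == 0) return(0)
  if (!debias) {
    abs(mean(imag_cs)) / denom
  } else {
    n <- length(imag_cs)
    num <- sum(imag_cs)^2 - sum(imag_cs^2)
    den <- sum(abs(imag_cs))^2 - sum(imag_cs^2)
    if (den <= 0) return(0)
    max(0, num / den)
  }
}

#' Ordinary band coherence (diagnostic)
#'
#' Magnitude of the normalized analytic cross-spectrum. Unlike the wPLI it
#' is inflated by zero-lag common sources; exposed as a debug/contrast
#' metric.
#'
#' @inheritParams wpli
#' @return Scalar in \[0, 1\].
#' @export
band_coherence <- function(x, y, fs, band, order = 3) {
  zx <- analytic_signal(butter_bandpass(x, fs, band[1], band[2], order))
  zy <- analytic_signal(butter_bandpass(y, fs, band[1], band[2], order))
  Mod(mean(zx * Conj(zy))) / sqrt(mean(Mod(zx)^2) * mean(Mod(zy)^2))
}

#' Windowed wPLI spectrogram
#'
#' One wPLI value per (time window, frequency bin): the band-pass /
#' analytic-signal step runs once per 1 Hz frequency bin over the whole
#' signal, then the index is formed within each non-overlapping window.
#'
#' @param x,y Numeric signals.
#' @param fs Sampling rate (Hz).
#' @param freq_range `c(lo, hi)` in Hz.
#' @param step Frequency step / bin width (Hz), default 1.
#' @param window_s Window length (s), default 60.
#' @return A `connectivity_track`: list with `times`, `freqs` (bin centers),
#'   `values` (time x freq), `metric = "wpli"`.
#' @export
wpli_spectrogram <- function(x, y, fs, freq_range = c(2, 100), step = 1,
                             window_s = 60) {
  if (freq_range[2] + step > fs / 2) abort("frequency range exceeds Nyquist")
  wlen <- round(window_s * fs)
  nwin <- floor(length(x) / wlen)
  if (nwin < 1) abort("signal shorter than one window")
  los <- seq(freq_range[1], freq_range[2] - step, by = step)
  vals <- matrix(NA_real_, nrow = nwin, ncol = length(los))
  for (j in seq_along(los)) {
    zx <- analytic_signal(butter_bandpass(x, fs, los[j], los[j] + step, 3))
    zy <- analytic_signal(butter_bandpass(y, fs, los[j], los[j] + step, 3))
    ics <- Im(zx * Conj(zy))
    for (w in seq_len(nwin)) {
      idx <- ((w - 1) * wlen + 1):(w * wlen)
      vals[w, j] <- wpli_from_imag(ics[idx])
    }
  }
  structure(list(times = (seq_len(nwin) - 0.5) * window_s,
                 freqs = los + step / 2, values = vals, metric = "wpli",
                 window_s = window_s),
            class = "connectivity_track")
}

# segment-averaged cross-spectral matrices within one epoch (Hanning
# windows, half-overlap), returning complex coherency on the segment grid
epoch_coherency <- function(x, y, fs, seg_len) {
  n <- length(x)
  shift <- floor(seg_len / 2)
  starts <- seq(1, n - seg_len + 1, by = shift)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  nf <- floor(seg_len / 2) + 1
  sxx <- syy <- numeric(nf)
  sxy <- complex(nf)
  for (s0 in starts) {
    idx <- s0:(s0 + seg_len - 1)
    X <- fft((x[idx] - mean(x[idx])) * win)[seq_len(nf)]
    Y <- fft((y[idx] - mean(y[idx])) * win)[seq_len(nf)]
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  denom <- sqrt(sxx * syy)
  denom[denom == 0] <- .Machine$double.eps
  sxy / denom
}

#' Phase slope index
#'
#' data2psi-style estimator: within each epoch the complex coherency is
#' estimated from Hanning-windowed, half-overlapping segments of
#' `seg_len_s` seconds; the PSI over the band is
#' `Im(sum_f Conj(C(f)) * C(f + df))` with `df = 1 / seg_len_s`. Epoch
#' values are averaged. Positive values mean `x` leads `y`; the estimator is
#' exactly antisymmetric under argument swap. Left un-normalized by default;
#' `normalize = TRUE` divides by the standard error over epochs.
#'
#' @param x,y Numeric signals of equal length.
#' @param fs Sampling rate (Hz).
#' @param band `c(lo, hi)` in Hz, at least `2 / seg_len_s` wide.
#' @param epoch_len_s Epoch length in seconds (default 60).
#' @param seg_len_s Segment length in seconds (default 1).
#' @param normalize Divide by the epoch-wise standard error (default
#'   `FALSE`).
#' @return Signed scalar.
#' @export
psi <- function(x, y, fs, band, epoch_len_s = 60, seg_len_s = 1,
                normalize = FALSE) {
  if (length(x) != length(y)) abort("signals must have equal length")
  seg_len <- round(seg_len_s * fs)
  epoch_len <- round(epoch_len_s * fs)
  if (length(x) < epoch_len) {
    epoch_len <- length(x)  # single shorter epoch
  }
  df <- 1 / seg_len_s
  if (diff(band) < df) abort("band narrower than the frequency resolution")
  freqs <- (seq_len(floor(seg_len / 2) + 1) - 1) * fs / seg_len
  sel <- which(freqs >= band[1] & freqs + df <= band[2])
  if (!length(sel)) abort("band contains no frequency-bin pairs")
  n_ep <- floor(length(x) / epoch_len)
  vals <- vapply(seq_len(n_ep), function(e) {
    idx <- ((e - 1) * epoch_len + 1):(e * epoch_len)
    C <- epoch_coherency(x[idx], y[idx], fs, seg_len)
    sum(Im(Conj(C[sel]) * C[sel + 1]))
  }, numeric(1))
  if (normalize && n_ep > 1) {
    se <- sd(vals) / sqrt(n_ep)
    if (se > 0) return(mean(vals) / se)
  }
  mean(vals)
}

#' Windowed PSI spectrogram
#'
#' PSI per (window, frequency bin) with a 2 Hz sliding frequency window;
#' swapping the channels negates the whole matrix exactly.
#'
#' @inheritParams wpli_spectrogram
#' @param step Frequency step (Hz), default 2.
#' @param seg_len_s Segment length within each window (s), default 1.
#' @return A `connectivity_track` with `metric = "psi"`.
#' @export
psi_spectrogram <- function(x, y, fs, freq_range = c(2, 100), step = 2,
                            window_s = 60, seg_len_s = 1) {
  wlen <- round(window_s * fs)
  nwin <- floor(length(x) / wlen)
  if (nwin < 1) abort("signal shorter than one window")
  los <- seq(freq_range[1], freq_range[2] - step, by = step)
  seg_len <- round(seg_len_s * fs)
  df <- 1 / seg_len_s
  freqs <- (seq_len(floor(seg_len / 2) + 1) - 1) * fs / seg_len
  vals <- matrix(NA_real_, nrow = nwin, ncol = length(los))
  for (w in seq_len(nwin)) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    C <- epoch_coherency(x[idx], y[idx], fs, seg_len)
    for (j in seq_along(los)) {
      sel <- which(freqs >= los[j] & freqs + df <= los[j] + step)
      if (!length(sel)) next
      vals[w, j] <- sum(Im(Conj(C[sel]) * C[sel + 1]))
    }
  }
  structure(list(times = (seq_len(nwin) - 0.5) * window_s,
                 freqs = los + step / 2, values = vals, metric = "psi",
                 window_s = window_s),
            class = "connectivity_track")
}

#' Circular time-shift surrogate null
#'
#' Recomputes a bivariate metric on circularly time-shifted copies of `y`
#' (uniform random shifts of at least `min_shift_s`), preserving both
#' autospectra while destroying the cross-phase relation.
#'
#' @param metric_fn Function `(x, y) -> scalar`.
#' @param x,y Numeric signals.
#' @param fs Sampling rate (Hz).
#' @param n Number of surrogates (default 100, minimum 19 recommended for a
#'   95th-percentile test; `n < 1` is an error).
#' @param min_shift_s Minimum shift in seconds (default 1).
#' @return A `surrogate_null` list with `values` and `quantiles`
#'   (2.5/5/50/95/97.5%).
#' @export
surrogate_null <- function(metric_fn, x, y, fs, n = 100, min_shift_s = 1) {
  if (!is_count(n) || n < 1) abort("`n` must be a positive count")
  nsmp <- length(y)
  min_shift <- round(min_shift_s * fs)
  if (min_shift < 1 || min_shift >= nsmp / 2) {
    abort("minimum shift must be at least 1 s and below half the signal")
  }
  vals <- vapply(seq_len(n), function(i) {
    shift <- sample(min_shift:(nsmp - min_shift), 1)
    ys <- c(y[(shift + 1):nsmp], y[seq_len(shift)])
    metric_fn(x, ys)
  }, numeric(1))
  structure(list(
    values = vals,
    quantiles = quantile(vals, c(0.025, 0.05, 0.5, 0.95, 0.975)),
    n = n, min_shift_s = min_shift_s
  ), class = "surrogate_null")
}

#' @export
print.connectivity_track <- function(x, ...) {
  cat(sprintf("<connectivity_track> %s: %d windows x %d freq bins\n",
              x$metric, length(x$times), length(x$freqs)))
  invisible(x)
}

#' Long-format view of a connectivity track
#'
#' @param x A `connectivity_track`.
#' @param ... Unused.
#' @return Tibble with `time`, `freq`, `value`, `metric`.
#' @export
tidy.connectivity_track <- function(x, ...) {
  tibble::tibble(
    time = rep(x$times, times = length(x$freqs)),
    freq = rep(x$freqs, each = length(x$times)),
    value = as.vector(x$values),
    metric = x$metric
  )
}
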