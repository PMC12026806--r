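# Multitaper spectral estimation, 1/f normalization, band power and
# baseline z-scoring.

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Exact DPSS tapers computed from the tridiagonal eigenproblem (Sturm
#' bisection plus inverse iteration, compiled). Columns are unit-norm.
#' Results are cached per `(n, nw, k)`.
#'
#' @param n Taper length (samples).
#' @param nw Time-half-bandwidth product (default 5).
#' @param k Number of tapers (default 9); must satisfy `k <= 2 * nw - 1`.
#' @return An `n` x `k` matrix.
#' @export
dpss_tapers <- function(n, nw = 5, k = 9) {
  if (k > 2 * nw - 1) abort("k must be <= 2 * nw - 1 for well-concentrated tapers")
  if (n < 2 * k) abort("window too short for the requested tapers")
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  if (!is.null(.neurodyn_cache[[key]])) return(.neurodyn_cache[[key]])
  tp <- .dpss_cpp(as.integer(n), nw, as.integer(k))
  .neurodyn_cache[[key]] <- tp
  tp
}

# one-sided PSD of one windowed segment, averaged over tapers
mt_psd_segment <- function(x, fs, tapers) {
  n <- length(x)
  k <- ncol(tapers)
  acc <- numeric(n)
  for (j in seq_len(k)) {
    X <- fft(x * tapers[, j])
    acc <- acc + (Mod(X)^2) / fs
  }
  two_sided <- acc / k
  nf <- floor(n / 2) + 1
  s <- two_sided[seq_len(nf)]
  if (n %% 2 == 0) {
    s[2:(nf - 1)] <- 2 * s[2:(nf - 1)]
  } else {
    s[2:nf] <- 2 * s[2:nf]
  }
  s
}

#' Multitaper power spectral density
#'
#' Slepian-taper eigenspectra averaged over `k` tapers, one-sided, in units
#' of power per Hz (so the PSD integrates to the signal variance).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param nw Time-half-bandwidth product (default 5).
#' @param k Number of tapers (default 9).
#' @return A tibble with columns `freq` (Hz) and `power`.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 10, by = 1e-3))
#' psd <- multitaper_psd(x, fs = 1000)
#' psd$freq[which.max(psd$power)]
#' @export
multitaper_psd <- function(x, fs, nw = 5, k = 9) {
  n <- length(x)
  tapers <- dpss_tapers(n, nw, k)
  s <- mt_psd_segment(x, fs, tapers)
  tibble::tibble(freq = (seq_along(s) - 1) * fs / n, power = s)
}

#' Windowed multitaper (or plain FFT) spectrogram
#'
#' One spectral estimate per non-overlapping window; a trailing partial
#' window is dropped.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param window_s Window length in seconds (default 60).
#' @param nw,k Multitaper parameters (defaults 5 and 9).
#' @param method `"multitaper"` or `"fft"` (single boxcar taper).
#' @return A `spectrogram` object: list with `times` (window centers, s),
#'   `freqs` (Hz), `power` (time x freq matrix), `norm_state`, `window_s`,
#'   `taper_params`.
#' @export
mt_spectrogram <- function(x, fs, window_s = 60, nw = 5, k = 9,
                           method = c("multitaper", "fft")) {
  method <- match.arg(method)
  wlen <- round(window_s * fs)
  nwin <- floor(length(x) / wlen)
  if (nwin < 1) abort("signal shorter than one window")
  tapers <- if (method == "multitaper") {
    dpss_tapers(wlen, nw, k)
  } else {
    matrix(1 / sqrt(wlen), nrow = wlen, ncol = 1)
  }
  nf <- floor(wlen / 2) + 1
  power <- matrix(0, nrow = nwin, ncol = nf)
  for (w in seq_len(nwin)) {
    seg <- x[((w - 1) * wlen + 1):(w * wlen)]
    power[w, ] <- mt_psd_segment(seg, fs, tapers)
  }
  structure(list(
    times = (seq_len(nwin) - 0.5) * window_s,
    freqs = (seq_len(nf) - 1) * fs / wlen,
    power = power,
    norm_state = "raw",
    window_s = window_s,
    taper_params = c(nw = if (method == "multitaper") nw else NA_real_,
                     k = ncol(tapers))
  ), class = "spectrogram")
}

#' 1/f normalization of a spectrogram
#'
#' Default method multiplies power by frequency (exact whitening of an
#' ideal 1/f spectrum); the f = 0 bin, for which the operation is undefined,
#' is dropped. The alternative divides by a power law fitted to the
#' session-mean spectrum over 1-100 Hz.
#'
#' @param spec A raw `spectrogram`.
#' @param method `"multiply"` (default) or `"fit"`.
#' @return A `spectrogram` with `norm_state = "one_over_f"`.
#' @export
one_over_f_normalize <- function(spec, method = c("multiply", "fit")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "spectrogram"))
  if (spec$norm_state != "raw") abort("spectrogram is already normalized")
  keep <- spec$freqs > 0
  f <- spec$freqs[keep]
  p <- spec$power[, keep, drop = FALSE]
  if (method == "multiply") {
    p <- sweep(p, 2, f, `*`)
  } else {
    mean_p <- colMeans(p)
    sel <- f >= 1 & f <= 100 & mean_p > 0
    fit <- lm(log(mean_p[sel]) ~ log(f[sel]))
    lawfun <- exp(coef(fit)[1]) * f^coef(fit)[2]
    p <- sweep(p, 2, lawfun, `/`)
  }
  spec$freqs <- f
  spec$power <- p
  spec$norm_state <- "one_over_f"
  spec
}

#' Band power series from a spectrogram
#'
#' Mean (not sum) of power over the frequency bins inside the band, per
#' time window; the mean keeps bands of unequal width comparable.
#'
#' @param spec A `spectrogram`.
#' @param band Either a power-band name (see [band_set()]) or `c(lo, hi)`
#'   in Hz.
#' @return A tibble with columns `time`, `band`, `power`.
#' @export
band_power <- function(spec, band) {
  stopifnot(inherits(spec, "spectrogram"))
  if (is.character(band)) {
    lim <- band_limits(band)
    label <- band
  } else {
    lim <- band
    label <- sprintf("%g-%g Hz", band[1], band[2])
  }
  sel <- spec$freqs >= lim[1] & spec$freqs <= lim[2]
  if (!any(sel)) {
    abort(sprintf("band [%g, %g] Hz contains no frequency bins", lim[1], lim[2]))
  }
  tibble::tibble(
    time = spec$times,
    band = label,
    power = rowMeans(spec$power[, sel, drop = FALSE])
  )
}

#' Z-score a per-window series against baseline windows
#'
#' Demeans by the baseline mean and scales by the baseline standard
#' deviation (sample SD, denominator `n - 1`).
#'
#' @param x Numeric per-window series.
#' @param baseline Logical mask or integer indices of baseline windows
#'   (at least 2, with nonzero variance).
#' @return Numeric z-score series, same length as `x`.
#' @export
zscore_to_baseline <- function(x, baseline) {
  idx <- if (is.logical(baseline)) which(baseline) else baseline
  if (length(idx) < 2) abort("need at least 2 baseline windows")
  b <- x[idx]
  s <- sd(b)
  if (!is.finite(s) || s == 0) abort("baseline has zero variance")
  (x - mean(b)) / s
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d windows x %d freqs (%g s windows, %s)\n",
              length(x$times), length(x$freqs), x$window_s, x$norm_state))
  invisible(x)
}

#' Long-format view of a spectrogram
#'
#' @param x A `spectrogram` object.
#' @param ... Unused.
#' @return Tibble with `time`, `freq`, `power`.
#' @export
tidy.spectrogram <- function(x, ...) {
  tibble::tibble(
    time = rep(x$times, times = length(x$freqs)),
    freq = rep(x$freqs, each = length(x$times)),
    power = as.vector(x$power)
  )
}
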