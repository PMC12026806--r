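# Shared numeric helpers: analytic signal, zero-phase filtering, seeds.

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal whose real part is `x` and whose
#' imaginary part is the Hilbert transform of `x`, computed by zeroing the
#' negative-frequency half of the spectrum and doubling the positive half.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) abort("signal too short for an analytic representation")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# FFT-based linear convolution of x with kernel b, keeping the central
# (zero group delay) portion. Requires symmetric b of odd length so that
# delay compensation by (length(b)-1)/2 is exact zero-phase.
fft_filt_zerophase <- function(x, b) {
  nb <- length(b)
  if (nb %% 2 == 0) abort("kernel must have odd length")
  n <- length(x)
  half <- (nb - 1L) / 2L
  # reflect-pad to suppress edge transients
  pad <- min(n - 1L, nb)
  xe <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[n - seq_len(pad)]))
  m <- stats::nextn(length(xe) + nb - 1L, c(2, 3, 5))
  X <- fft(c(xe, numeric(m - length(xe))))
  B <- fft(c(b, numeric(m - nb)))
  y <- Re(fft(X * B, inverse = TRUE)) / m
  y[(pad + half) + seq_len(n)]
}

# Zero-phase FIR band-pass (Hamming window design via signal::fir1).
# Order defaults to 3 cycles of the low cutoff, forced even.
fir_bandpass <- function(x, fs, lo, hi, cycles = 3) {
  nyq <- fs / 2
  if (lo <= 0 || hi >= nyq || lo >= hi) {
    abort(sprintf("invalid band [%g, %g] Hz at fs = %g Hz", lo, hi, fs))
  }
  ord <- ceiling(cycles * fs / lo)
  if (ord %% 2 == 1) ord <- ord + 1
  ord <- min(ord, length(x) - 1 - (length(x) %% 2 == 0))
  if (ord %% 2 == 1) ord <- ord - 1
  if (ord < 6) abort("signal too short to filter this band")
  b <- signal::fir1(ord, c(lo, hi) / nyq, type = "pass")
  fft_filt_zerophase(x, as.numeric(b))
}

# Zero-phase Butterworth band-pass (forward-backward), order per call site.
butter_bandpass <- function(x, fs, lo, hi, order = 3) {
  nyq <- fs / 2
  if (lo <= 0 || hi >= nyq || lo >= hi) {
    abort(sprintf("invalid band [%g, %g] Hz at fs = %g Hz", lo, hi, fs))
  }
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Deterministic child seeds below 2^31: splitmix-style integer hash of a
# master seed and stream indices, so adding one stream never perturbs others.
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) * 10007 + 12345) %% 2147483647
  }
  as.integer(h)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == floor(x)

stopifnot_scalar_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    abort(sprintf("`%s` must be a probability in [0, 1]", name))
  }
}
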