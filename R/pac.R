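# Phase-amplitude coupling: Tort modulation index, comodulograms, ROI
# quantification, and circular-shift surrogate nulls.

#' Comodulogram grid
#'
#' Default analysis grid: phase-frequency centers 0-15 Hz in 1 Hz steps with
#' 4 Hz bandwidth; amplitude-frequency centers 10-250 Hz in 5 Hz steps with
#' 10 Hz bandwidth. Cells whose phase band would extend below 0.5 Hz are
#' masked as invalid (the band-pass is undefined there), as are amplitude
#' cells whose band exceeds the Nyquist frequency of the signal at hand.
#'
#' @param phase_centers,amp_centers Band centers in Hz.
#' @param phase_bw,amp_bw Full bandwidths in Hz.
#' @param n_bins Number of phase bins for the modulation index (default 18).
#' @param window_s Analysis window in seconds: 60 for quantification,
#'   300 for overview maps.
#' @return A `pac_grid` list.
#' @export
pac_grid <- function(phase_centers = seq(0, 15, by = 1),
                     amp_centers = seq(10, 250, by = 5),
                     phase_bw = 4, amp_bw = 10,
                     n_bins = 18, window_s = 60) {
  if (phase_bw <= 0 || amp_bw <= 0) abort("bandwidths must be positive")
  if (n_bins < 2) abort("need at least 2 phase bins")
  structure(list(phase_centers = phase_centers, amp_centers = amp_centers,
                 phase_bw = phase_bw, amp_bw = amp_bw, n_bins = n_bins,
                 window_s = window_s), class = "pac_grid")
}

#' Extract instantaneous phase and amplitude
#'
#' Band-passes the signal with a zero-phase FIR filter (Hamming design,
#' order three cycles of the low cutoff) and takes phase and magnitude of
#' the analytic signal.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param phase_band,amp_band `c(lo, hi)` in Hz; either may be `NULL` to
#'   skip that component.
#' @return List with `phase` (radians in (-pi, pi]) and/or `amplitude`.
#' @export
extract_phase_amp <- function(x, fs, phase_band = NULL, amp_band = NULL) {
  out <- list()
  if (!is.null(phase_band)) {
    xf <- fir_bandpass(x, fs, phase_band[1], phase_band[2])
    out$phase <- Arg(analytic_signal(xf))
  }
  if (!is.null(amp_band)) {
    xa <- fir_bandpass(x, fs, amp_band[1], amp_band[2])
    out$amplitude <- Mod(analytic_signal(xa))
  }
  out
}

# fast binned-mean helper: returns per-bin mean amplitude (NaN when empty)
binned_amp_means <- function(bins, amplitude, n_bins) {
  sums <- as.vector(rowsum(c(amplitude, numeric(n_bins)),
                           c(bins, seq_len(n_bins)), reorder = TRUE))
  counts <- tabulate(bins, nbins = n_bins)
  sums / counts
}

#' Tort modulation index
#'
#' Phases are binned into `n_bins` equal bins over (-pi, pi]; the normalized
#' mean-amplitude distribution P across bins is compared to uniform via its
#' Shannon entropy H: MI = (log N - H) / log N, in \[0, 1\]. MI is invariant
#' to positive scaling of the amplitude series (up to floating-point
#' rounding in the bin sums). An empty phase bin
#' triggers a documented fallback (a uniform epsilon mass is added and the
#' result carries attribute `empty_bins`).
#'
#' @param phase Phase series in radians.
#' @param amplitude Nonnegative amplitude series, same length.
#' @param n_bins Number of phase bins (default 18).
#' @return Scalar MI in \[0, 1\].
#' @export
modulation_index <- function(phase, amplitude, n_bins = 18) {
  if (length(phase) != length(amplitude)) {
    abort("phase and amplitude must have equal length")
  }
  if (n_bins < 2) abort("need at least 2 phase bins")
  bins <- floor((phase + pi) / (2 * pi / n_bins)) + 1
  bins[bins > n_bins] <- n_bins   # phase exactly -pi maps to bin 1; pi to N
  bins[bins < 1] <- 1
  m <- binned_amp_means(bins, amplitude, n_bins)
  empty <- !is.finite(m)
  if (any(empty)) {
    m[empty] <- 0
    m <- m + max(m, .Machine$double.eps) * 1e-12
  }
  tot <- sum(m)
  if (tot == 0) return(0)
  p <- m / tot
  nz <- p > 0
  h <- -sum(p[nz] * log(p[nz]))
  mi <- (log(n_bins) - h) / log(n_bins)
  if (any(empty)) attr(mi, "empty_bins") <- which(empty)
  mi
}

# valid-cell masks for a grid at sampling rate fs
grid_masks <- function(grid, fs) {
  phase_ok <- (grid$phase_centers - grid$phase_bw / 2) >= 0.5
  amp_ok <- (grid$amp_centers + grid$amp_bw / 2) <= fs / 2 &
    (grid$amp_centers - grid$amp_bw / 2) > 0
  list(phase = phase_ok, amp = amp_ok)
}

#' Comodulogram
#'
#' Modulation index for every valid (phase center, amplitude center) cell of
#' the grid, computed over the supplied signal. Masked cells are `NA`.
#'
#' @param x Numeric signal (at least `grid$window_s` seconds are expected
#'   for stable estimates).
#' @param fs Sampling rate (Hz).
#' @param grid A [pac_grid()].
#' @return A `comodulogram`: list with `phase_freqs`, `amp_freqs`, `mi`
#'   (phase x amp matrix), `n_bins`.
#' @export
comodulogram <- function(x, fs, grid = pac_grid()) {
  masks <- grid_masks(grid, fs)
  np <- length(grid$phase_centers)
  na <- length(grid$amp_centers)
  nb <- grid$n_bins

  phase_bins <- vector("list", np)
  for (i in seq_len(np)) {
    if (!masks$phase[i]) next
    pc <- grid$phase_centers[i]
    ph <- extract_phase_amp(x, fs,
      phase_band = c(pc - grid$phase_bw / 2, pc + grid$phase_bw / 2))$phase
    b <- floor((ph + pi) / (2 * pi / nb)) + 1
    b[b > nb] <- nb
    phase_bins[[i]] <- b
  }
  amp_env <- vector("list", na)
  for (j in seq_len(na)) {
    if (!masks$amp[j]) next
    ac <- grid$amp_centers[j]
    amp_env[[j]] <- extract_phase_amp(x, fs,
      amp_band = c(ac - grid$amp_bw / 2, ac + grid$amp_bw / 2))$amplitude
  }

  mi <- matrix(NA_real_, nrow = np, ncol = na,
               dimnames = list(grid$phase_centers, grid$amp_centers))
  for (i in seq_len(np)) {
    if (!masks$phase[i]) next
    for (j in seq_len(na)) {
      if (!masks$amp[j]) next
      m <- binned_amp_means(phase_bins[[i]], amp_env[[j]], nb)
      m[!is.finite(m)] <- 0
      tot <- sum(m)
      if (tot == 0) { mi[i, j] <- 0; next }
      p <- m / tot
      nz <- p > 0
      mi[i, j] <- (log(nb) + sum(p[nz] * log(p[nz]))) / log(nb)
    }
  }
  structure(list(phase_freqs = grid$phase_centers,
                 amp_freqs = grid$amp_centers,
                 mi = mi, n_bins = nb, fs = fs, grid = grid),
            class = "comodulogram")
}

#' ROI mean of a comodulogram
#'
#' Unweighted mean of the MI cells whose centers fall inside the ROI ranges
#' (inclusive); masked (NA) cells are excluded.
#'
#' @param com A `comodulogram`.
#' @param roi A one-row tibble from [pac_rois()] or a list with `phase_lo`,
#'   `phase_hi`, `amp_lo`, `amp_hi`.
#' @return Scalar mean MI.
#' @export
roi_mean <- function(com, roi) {
  stopifnot(inherits(com, "comodulogram"))
  pi_ <- com$phase_freqs >= roi$phase_lo & com$phase_freqs <= roi$phase_hi
  ai <- com$amp_freqs >= roi$amp_lo & com$amp_freqs <= roi$amp_hi
  if (!any(pi_) || !any(ai)) abort("ROI does not intersect the grid")
  cells <- com$mi[pi_, ai, drop = FALSE]
  if (all(is.na(cells))) abort("ROI covers only masked cells")
  mean(cells, na.rm = TRUE)
}

#' Windowed ROI coupling series
#'
#' Modulation index averaged over the ROI cells, per non-overlapping window
#' — the quantification path (60 s windows by default). Phase and amplitude
#' are extracted once on the full signal, then sliced per window.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param roi ROI spec (see [roi_mean()]).
#' @param grid A [pac_grid()] supplying bandwidths, bins and window length.
#' @return A tibble with columns `time` (window center, s) and `mi`.
#' @export
pac_roi_series <- function(x, fs, roi, grid = pac_grid()) {
  wlen <- round(grid$window_s * fs)
  nwin <- floor(length(x) / wlen)
  if (nwin < 1) abort("signal shorter than one window")
  masks <- grid_masks(grid, fs)
  pc_all <- grid$phase_centers
  ac_all <- grid$amp_centers
  pc <- pc_all[pc_all >= roi$phase_lo & pc_all <= roi$phase_hi & masks$phase]
  ac <- ac_all[ac_all >= roi$amp_lo & ac_all <= roi$amp_hi & masks$amp]
  if (!length(pc) || !length(ac)) abort("ROI covers no valid grid cells")
  nb <- grid$n_bins

  bins <- lapply(pc, function(p) {
    ph <- extract_phase_amp(x, fs,
      phase_band = c(p - grid$phase_bw / 2, p + grid$phase_bw / 2))$phase
    b <- floor((ph + pi) / (2 * pi / nb)) + 1
    b[b > nb] <- nb
    b
  })
  envs <- lapply(ac, function(a) {
    extract_phase_amp(x, fs,
      amp_band = c(a - grid$amp_bw / 2, a + grid$amp_bw / 2))$amplitude
  })

  out <- numeric(nwin)
  for (w in seq_len(nwin)) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    acc <- 0
    for (b in bins) {
      bw_ <- b[idx]
      for (e in envs) {
        m <- binned_amp_means(bw_, e[idx], nb)
        m[!is.finite(m)] <- 0
        tot <- sum(m)
        if (tot == 0) next
        p <- m / tot
        nz <- p > 0
        acc <- acc + (log(nb) + sum(p[nz] * log(p[nz]))) / log(nb)
      }
    }
    out[w] <- acc / (length(bins) * length(envs))
  }
  tibble::tibble(time = (seq_len(nwin) - 0.5) * grid$window_s, mi = out)
}

#' Circular-shift surrogate null for an ROI modulation index
#'
#' Recomputes the ROI MI after circularly shifting each amplitude envelope
#' relative to phase by random offsets of at least `min_shift_s`, which
#' preserves the spectra of both series while destroying their alignment.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param roi ROI spec.
#' @param grid A [pac_grid()].
#' @param n Number of surrogates (default 19).
#' @param min_shift_s Minimum shift in seconds (default 1).
#' @return Numeric vector of surrogate ROI MI values.
#' @export
pac_surrogate_null <- function(x, fs, roi, grid = pac_grid(), n = 19,
                               min_shift_s = 1) {
  if (n < 1) abort("need at least one surrogate")
  masks <- grid_masks(grid, fs)
  pc <- grid$phase_centers[grid$phase_centers >= roi$phase_lo &
                           grid$phase_centers <= roi$phase_hi & masks$phase]
  ac <- grid$amp_centers[grid$amp_centers >= roi$amp_lo &
                         grid$amp_centers <= roi$amp_hi & masks$amp]
  nb <- grid$n_bins
  nsmp <- length(x)
  min_shift <- round(min_shift_s * fs)
  if (min_shift >= nsmp / 2) abort("signal too short for the minimum shift")

  bins <- lapply(pc, function(p) {
    ph <- extract_phase_amp(x, fs,
      phase_band = c(p - grid$phase_bw / 2, p + grid$phase_bw / 2))$phase
    b <- floor((ph + pi) / (2 * pi / nb)) + 1
    b[b > nb] <- nb
    b
  })
  envs <- lapply(ac, function(a) {
    extract_phase_amp(x, fs,
      amp_band = c(a - grid$amp_bw / 2, a + grid$amp_bw / 2))$amplitude
  })

  vapply(seq_len(n), function(i) {
    shift <- sample(min_shift:(nsmp - min_shift), 1)
    acc <- 0
    for (b in bins) {
      for (e in envs) {
        es <- c(e[(shift + 1):nsmp], e[seq_len(shift)])
        m <- binned_amp_means(b, es, nb)
        m[!is.finite(m)] <- 0
        tot <- sum(m)
        if (tot == 0) next
        p <- m / tot
        nz <- p > 0
        acc <- acc + (log(nb) + sum(p[nz] * log(p[nz]))) / log(nb)
      }
    }
    acc / (length(bins) * length(envs))
  }, numeric(1))
}

#' @export
print.comodulogram <- function(x, ...) {
  cat(sprintf("<comodulogram> %d phase x %d amplitude centers, %d bins\n",
              length(x$phase_freqs), length(x$amp_freqs), x$n_bins))
  cat(sprintf("  peak MI %.4g at phase %g Hz / amp %g Hz\n",
              max(x$mi, na.rm = TRUE),
              x$phase_freqs[which(x$mi == max(x$mi, na.rm = TRUE),
                                  arr.ind = TRUE)[1, 1]],
              x$amp_freqs[which(x$mi == max(x$mi, na.rm = TRUE),
                                arr.ind = TRUE)[1, 2]]))
  invisible(x)
}

#' Long-format view of a comodulogram
#'
#' @param x A `comodulogram` object.
#' @param ... Unused.
#' @return Tibble with `phase_freq`, `amp_freq`, `mi`.
#' @export
tidy.comodulogram <- function(x, ...) {
  tibble::tibble(
    phase_freq = rep(x$phase_freqs, times = length(x$amp_freqs)),
    amp_freq = rep(x$amp_freqs, each = length(x$phase_freqs)),
    mi = as.vector(x$mi)
  )
}
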