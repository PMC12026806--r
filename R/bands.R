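#' Frequency band definitions
#'
#' Band sets are kept role-specific rather than unified, because the
#' conventional limits differ by analysis: the power bands use theta 8-12 Hz
#' and low gamma 30-48 Hz, while the coherence quantification uses low gamma
#' 20-40 Hz and the directionality analysis uses theta 4-10 Hz.
#'
#' @param role One of `"power"`, `"coherence"`, `"directionality"`.
#' @return A tibble with columns `band`, `lo`, `hi` (Hz).
#' @examples
#' band_set("power")
#' @export
band_set <- function(role = c("power", "coherence", "directionality")) {
  role <- match.arg(role)
  out <- switch(role,
    power = tibble::tribble(
      ~band, ~lo, ~hi,
      "delta",        2,   5,
      "theta",        8,  12,
      "beta",        18,  25,
      "low_gamma",   30,  48,
      "high_gamma",  52, 100,
      "high_freq",  100, 200,
      "hf_low",     100, 150,
      "hf_high",    150, 200
    ),
    coherence = tibble::tribble(
      ~band, ~lo, ~hi,
      "theta",     8, 12,
      "low_gamma", 20, 40
    ),
    directionality = tibble::tribble(
      ~band, ~lo, ~hi,
      "theta", 4, 10
    )
  )
  out
}

band_limits <- function(name, role = "power") {
  bs <- band_set(role)
  row <- bs[bs$band == name, ]
  if (nrow(row) != 1) abort(sprintf("unknown %s band '%s'", role, name))
  c(row$lo, row$hi)
}

#' Comodulogram regions of interest
#'
#' Default ROIs for phase-amplitude coupling quantification, plus the
#' results-section variants that differ slightly from the methods defaults
#' (the CA1 delta-high-frequency ROI that emerges under the sPCP phenotype,
#' and a wider prelimbic delta-high-gamma ROI). ROIs are plain rows so users
#' can add their own.
#'
#' @param preset `"methods"` (default quantification set) or `"results"`
#'   (the variant ranges reported alongside the sPCP phenotype).
#' @return A tibble with columns `roi`, `region`, `phase_lo`, `phase_hi`,
#'   `amp_lo`, `amp_hi` (Hz).
#' @examples
#' pac_rois()
#' pac_rois("results")
#' @export
pac_rois <- function(preset = c("methods", "results")) {
  preset <- match.arg(preset)
  switch(preset,
    methods = tibble::tribble(
      ~roi,                 ~region, ~phase_lo, ~phase_hi, ~amp_lo, ~amp_hi,
      "ca1_theta_hg",       "CA1",          5,        10,      50,     100,
      "pl_delta_hg",        "PL",           2,         6,      75,     100,
      "pl_theta_hf",        "PL",           4,        10,     150,     200
    ),
    results = tibble::tribble(
      ~roi,                 ~region, ~phase_lo, ~phase_hi, ~amp_lo, ~amp_hi,
      "ca1_delta_hf",       "CA1",          2,         5,     150,     200,
      "pl_delta_hg_wide",   "PL",           2,         5,      75,     120
    )
  )
}
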