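# Accelerometer mobility and novel-object-recognition metrics.

#' Accelerometer mobility series
#'
#' Instantaneous acceleration module `m_t = sqrt(x^2 + y^2 + z^2)`, its
#' variance in non-overlapping bins (1 min by default; a trailing partial
#' bin is dropped), and the per-bin ratio to the highest baseline value.
#' The ratio is invariant to a uniform gain on all three axes.
#'
#' @param acc 3 x samples numeric matrix (x, y, z).
#' @param fs Sampling rate (Hz).
#' @param bin_s Bin length in seconds (default 60).
#' @param baseline_bins Logical mask or integer indices of baseline bins
#'   (default: all bins).
#' @return A tibble with columns `time` (bin center, s), `variance`,
#'   `ratio`.
#' @export
acc_mobility <- function(acc, fs, bin_s = 60, baseline_bins = NULL) {
  if (!is.matrix(acc) || nrow(acc) != 3) {
    abort("`acc` must be a 3 x samples matrix")
  }
  blen <- round(bin_s * fs)
  nb <- floor(ncol(acc) / blen)
  if (nb < 1) abort("recording shorter than one bin")
  m <- sqrt(colSums(acc^2))
  v <- vapply(seq_len(nb), function(b) {
    var(m[((b - 1) * blen + 1):(b * blen)])
  }, numeric(1))
  idx <- if (is.null(baseline_bins)) seq_len(nb) else {
    if (is.logical(baseline_bins)) which(baseline_bins) else baseline_bins
  }
  peak <- max(v[idx])
  tibble::tibble(
    time = (seq_len(nb) - 0.5) * bin_s,
    variance = v,
    ratio = if (peak > 0) v / peak else rep(NA_real_, nb)
  )
}

#' Discrimination index
#'
#' `DI = (t_novel - t_familiar) / (t_novel + t_familiar)`, in \[-1, 1\];
#' negative values indicate a preference for the familiar object. Zero total
#' exploration leaves the index undefined (`NA` with attribute
#' `flagged = TRUE`, the animal-exclusion convention), never 0.
#'
#' @param t_novel,t_familiar Exploration seconds for the novel and familiar
#'   object.
#' @return Scalar DI, or flagged `NA` when undefined.
#' @examples
#' discrimination_index(30, 10)  # 0.5
#' @export
discrimination_index <- function(t_novel, t_familiar) {
  if (t_novel < 0 || t_familiar < 0) abort("exploration times must be >= 0")
  total <- t_novel + t_familiar
  if (total == 0) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  (t_novel - t_familiar) / total
}

#' Exploration and discrimination summary of a visit table
#'
#' Totals exploration seconds per object (and per grouping column if
#' present), and derives the discrimination index from the totals.
#'
#' @param visits Tibble with columns `object` (`"novel"`/`"familiar"`),
#'   `duration_s`, and optionally grouping columns (e.g. `phase`,
#'   `animal_id`, `condition`).
#' @param group_by Character vector of grouping columns (default: `phase`
#'   if present).
#' @return A tibble with per-group `t_novel`, `t_familiar`,
#'   `total_exploration_s`, `n_visits`, `di`.
#' @export
exploration_summary <- function(visits, group_by = intersect("phase", names(visits))) {
  if (nrow(visits) == 0) {
    abort("empty visit table")
  }
  if (!all(c("object", "duration_s") %in% names(visits))) {
    abort("visit table needs `object` and `duration_s` columns")
  }
  out <- visits |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      t_novel = sum(.data$duration_s[.data$object == "novel"]),
      t_familiar = sum(.data$duration_s[.data$object == "familiar"]),
      total_exploration_s = sum(.data$duration_s),
      n_visits = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(di = ifelse(.data$total_exploration_s > 0,
      (.data$t_novel - .data$t_familiar) /
        (.data$t_novel + .data$t_familiar), NA_real_))
  out
}

#' Group mean and standard error of exploration metrics
#'
#' @param summaries Output of [exploration_summary()] with an `animal_id`
#'   column (one row per animal and group).
#' @param metric Column to summarise (default `"total_exploration_s"`).
#' @param group_by Grouping columns (default `"phase"` if present).
#' @return Tibble with `n`, `mean`, `sem` per group.
#' @export
group_exploration <- function(summaries, metric = "total_exploration_s",
                              group_by = intersect("phase", names(summaries))) {
  summaries |>
    dplyr::filter(is.finite(.data[[metric]])) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[metric]]),
      sem = if (dplyr::n() > 1) sd(.data[[metric]]) / sqrt(dplyr::n()) else 0,
      .groups = "drop"
    )
}
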