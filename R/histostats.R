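# Histology co-expression aggregation: per-section counts -> per-animal
# summaries -> sex-stratified and pooled group rows.

#' Per-animal histology summary
#'
#' For each animal, region and marker: the mean marker-positive count per
#' section and the co-expression percentage. The default pools cells across
#' sections (`100 * sum(coexpress) / sum(marker)`), which is more stable
#' when per-section counts are small; `percent = "mean_of_sections"`
#' averages the section-wise percentages instead. Animals with zero marker
#' cells get `NA` percent and `flagged = TRUE`.
#'
#' @param counts Tibble with columns `animal_id`, `sex`, `region`, `marker`,
#'   `section_id`, `n_marker_pos`, `n_coexpress`.
#' @param percent `"pooled"` (default) or `"mean_of_sections"`.
#' @return Tibble with `animal_id`, `sex`, `region`, `marker`, `n_sections`,
#'   `mean_count`, `pct_coexpress`, `flagged`.
#' @export
per_animal_summary <- function(counts, percent = c("pooled", "mean_of_sections")) {
  percent <- match.arg(percent)
  need <- c("animal_id", "sex", "region", "marker", "n_marker_pos", "n_coexpress")
  if (!all(need %in% names(counts))) {
    abort(paste("count table needs columns:", paste(need, collapse = ", ")))
  }
  if (any(counts$n_coexpress > counts$n_marker_pos)) {
    abort("co-expression counts exceed marker-positive counts")
  }
  counts |>
    dplyr::group_by(.data$animal_id, .data$sex, .data$region, .data$marker) |>
    dplyr::summarise(
      n_sections = dplyr::n(),
      mean_count = mean(.data$n_marker_pos),
      pct_coexpress = if (percent == "pooled") {
        if (sum(.data$n_marker_pos) > 0) {
          100 * sum(.data$n_coexpress) / sum(.data$n_marker_pos)
        } else NA_real_
      } else {
        ok <- .data$n_marker_pos > 0
        if (any(ok)) {
          mean(100 * .data$n_coexpress[ok] / .data$n_marker_pos[ok])
        } else NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = is.na(.data$pct_coexpress))
}

#' Sex-stratified and pooled group summary
#'
#' Unweighted mean and SEM over animals within each sex, plus an "all" row
#' per region and marker. The pooled "all" mean over animals equals the
#' animal-count-weighted mean of the sex means exactly (before rounding),
#' which is how the published per-sex rows collapse into the pooled rows.
#'
#' @param per_animal Output of [per_animal_summary()].
#' @param value Column to summarise (default `"pct_coexpress"`).
#' @return Tibble with `region`, `marker`, `sex` (including `"all"`), `n`,
#'   `mean`, `sem`.
#' @export
group_summary <- function(per_animal, value = "pct_coexpress") {
  dat <- per_animal |> dplyr::filter(is.finite(.data[[value]]))
  by_sex <- dat |>
    dplyr::group_by(.data$region, .data$marker, .data$sex) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      sem = if (dplyr::n() > 1) sd(.data[[value]]) / sqrt(dplyr::n()) else 0,
      .groups = "drop"
    )
  pooled <- dat |>
    dplyr::group_by(.data$region, .data$marker) |>
    dplyr::summarise(
      sex = "all",
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      sem = if (dplyr::n() > 1) sd(.data[[value]]) / sqrt(dplyr::n()) else 0,
      .groups = "drop"
    )
  dplyr::bind_rows(by_sex, pooled)
}

#' Pool sex-stratified means into an overall mean
#'
#' Animal-count-weighted mean of per-sex means: with per-animal data the
#' result equals the plain mean over all animals. This is the operator that
#' reconstructs a published pooled row from its per-sex rows.
#'
#' @param means Per-sex mean values.
#' @param ns Per-sex animal counts.
#' @return Scalar pooled mean.
#' @examples
#' pooled_mean(c(53, 50), c(5, 4))  # 51.67 -> prints as 52
#' @export
pooled_mean <- function(means, ns) {
  if (length(means) != length(ns) || !length(means)) {
    abort("`means` and `ns` must be equal-length, nonempty")
  }
  sum(means * ns) / sum(ns)
}

#' Welch t-test between sexes
#'
#' Two-sample (Welch) comparison of per-animal percentages between female
#' and male animals for one region and marker, with Cohen's d (pooled-SD
#' denominator) as effect size.
#'
#' @param per_animal Output of [per_animal_summary()].
#' @param region,marker Cell to test.
#' @param value Column to compare (default `"pct_coexpress"`).
#' @return One-row tibble with `region`, `marker`, `t`, `df`, `p`,
#'   `cohens_d`, `n_female`, `n_male`.
#' @export
sex_comparison <- function(per_animal, region, marker,
                           value = "pct_coexpress") {
  dat <- per_animal |>
    dplyr::filter(.data$region == !!region, .data$marker == !!marker,
                  is.finite(.data[[value]]))
  f <- dat[[value]][dat$sex == "female"]
  m <- dat[[value]][dat$sex == "male"]
  if (length(f) < 2 || length(m) < 2) {
    abort("need at least two animals of each sex")
  }
  if (sd(f) == 0 && sd(m) == 0 && mean(f) == mean(m)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(f) + length(m) - 2),
               p.value = 1)
  } else {
    tt <- stats::t.test(f, m)
  }
  sp <- sqrt(((length(f) - 1) * var(f) + (length(m) - 1) * var(m)) /
             (length(f) + length(m) - 2))
  tibble::tibble(
    region = region, marker = marker,
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value,
    cohens_d = if (sp > 0) (mean(f) - mean(m)) / sp else 0,
    n_female = length(f), n_male = length(m)
  )
}

#' Published co-expression reference rows
#'
#' Sex-stratified summary rows (animal counts, mean marker-positive counts
#' per section, and co-expression percentages, mean +/- SEM) for PV and SST
#' markers across the six regions, as printed in the source study's summary
#' table. Used to check that the pooled operator reconstructs the printed
#' "all" rows.
#'
#' @return Tibble with `region`, `marker`, `sex`, `n`, `mean_count`,
#'   `mean_count_sem`, `pct_coexpress`, `pct_sem`.
#' @export
coexpression_reference <- function() {
  path <- system.file("extdata", "coexpression_reference.csv",
                      package = "neurodyn", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
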