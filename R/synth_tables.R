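# Synthetic behavior and histology tables.

#' Generate a novel-object-recognition visit table
#'
#' Visits alternate randomly between the novel and the familiar object with
#' probability `p_novel` of targeting the novel one; visit durations are
#' i.i.d. exponential with mean `mean_visit_s`, so the expected
#' discrimination index converges to `2 * p_novel - 1`.
#'
#' @param n_visits Number of visits.
#' @param p_novel Probability that a visit targets the novel object.
#' @param mean_visit_s Mean visit duration in seconds.
#' @param phase Task phase label attached to every row.
#' @param seed Integer seed.
#' @return A tibble with columns `timestamp_s`, `object`, `duration_s`,
#'   `phase`. Zero visits yields an empty table with attribute
#'   `flagged = TRUE`.
#' @examples
#' gen_visit_table(20, p_novel = 0.75, seed = 1)
#' @export
gen_visit_table <- function(n_visits, p_novel = 0.5, mean_visit_s = 5,
                            phase = "STM", seed = 1L) {
  if (!is_count(n_visits)) abort("`n_visits` must be a nonnegative count")
  stopifnot_scalar_prob(p_novel, "p_novel")
  if (mean_visit_s <= 0) abort("`mean_visit_s` must be positive")
  if (n_visits == 0) {
    out <- tibble::tibble(timestamp_s = numeric(), object = character(),
                          duration_s = numeric(), phase = character())
    attr(out, "flagged") <- TRUE
    return(out)
  }
  set.seed(as.integer(seed))
  object <- ifelse(runif(n_visits) < p_novel, "novel", "familiar")
  duration <- rexp(n_visits, rate = 1 / mean_visit_s)
  gaps <- rexp(n_visits, rate = 1 / 10)
  timestamp <- cumsum(gaps + c(0, duration[-n_visits]))
  tibble::tibble(timestamp_s = timestamp, object = object,
                 duration_s = duration, phase = phase)
}

#' Generate a per-section histology count table
#'
#' Emulates per-section immunohistochemistry counts: marker-positive cells
#' per section are Poisson with rate `marker_rate`, and each marker-positive
#' cell co-expresses the receptor independently with probability
#' `coexpr_prob`, so co-expression counts are binomial.
#'
#' @param n_animals_per_sex Named counts, e.g. `c(female = 5, male = 4)`.
#' @param sections_per_animal Sections counted per animal and region.
#' @param marker_rate Expected marker-positive cells per section (scalar or
#'   named per-region vector).
#' @param coexpr_prob Probability that a marker-positive cell co-expresses
#'   the receptor (scalar or named per-region vector).
#' @param regions Character vector of regions.
#' @param marker Marker label.
#' @param seed Integer seed.
#' @return A tibble with columns `animal_id`, `sex`, `region`, `marker`,
#'   `section_id`, `n_marker_pos`, `n_coexpress`.
#' @examples
#' gen_count_table(c(female = 2, male = 2), sections_per_animal = 3,
#'                 marker_rate = 25, coexpr_prob = 0.5, seed = 1)
#' @export
gen_count_table <- function(n_animals_per_sex = c(female = 5, male = 4),
                            sections_per_animal = 3,
                            marker_rate = 25,
                            coexpr_prob = 0.5,
                            regions = c("CA1", "CA3", "DG", "ACC", "PL", "IL"),
                            marker = "PV",
                            seed = 1L) {
  if (is.null(names(n_animals_per_sex))) {
    abort("`n_animals_per_sex` must be named by sex")
  }
  if (!is_count(sections_per_animal) || sections_per_animal < 1) {
    abort("`sections_per_animal` must be a positive count")
  }
  for (p in coexpr_prob) stopifnot_scalar_prob(p, "coexpr_prob")
  set.seed(as.integer(seed))
  rows <- list()
  idx <- 0
  for (sex in names(n_animals_per_sex)) {
    for (a in seq_len(n_animals_per_sex[[sex]])) {
      idx <- idx + 1
      animal <- sprintf("%s_%02d", substr(sex, 1, 1), idx)
      for (region in regions) {
        rate <- if (length(marker_rate) > 1) marker_rate[[region]] else marker_rate
        p <- if (length(coexpr_prob) > 1) coexpr_prob[[region]] else coexpr_prob
        n_pos <- rpois(sections_per_animal, rate)
        n_co <- rbinom(sections_per_animal, n_pos, p)
        rows[[length(rows) + 1]] <- tibble::tibble(
          animal_id = animal, sex = sex, region = region, marker = marker,
          section_id = seq_len(sections_per_animal),
          n_marker_pos = n_pos, n_coexpress = n_co
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
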