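#' Single-hospital view of the claims (facility-survey style definition)
#'
#' Emulates the admission definition of annual facility surveys, which see
#' only what happens inside one hospital: every stay that is not a
#' continuation of a previous stay in the *same* hospital counts as one
#' admission, a transfer out (destination `other_hospital`) is not a
#' community discharge, and follow-up ends with that hospital's records.
#' Under this definition an episode with one inter-hospital transfer counts
#' as two admissions and its community discharge is only visible at the
#' receiving hospital.
#'
#' @param stays Raw stay table (pre-linkage).
#' @param window_start,window_end Admission window for the pseudo-admission
#'   counts.
#' @param gap_days Within-hospital chaining tolerance (default 1, matching
#'   the episode linkage rule).
#' @return A tibble of pseudo-admissions with `patient_id`, `hospital_id`,
#'   `prefecture`, admission/discharge dates, `destination`, demographics,
#'   and `discharged_community` (logical, `FALSE` for transfers out and
#'   still-open stays).
#' @export
single_hospital_view <- function(stays,
                                 window_start = as.Date("2014-04-01"),
                                 window_end = as.Date("2016-03-31"),
                                 gap_days = 1L) {
  validate_stays(stays)
  pseudo <- stays |>
    dplyr::arrange(.data$patient_id, .data$hospital_id, .data$admit_date,
                   is.na(.data$discharge_date), .data$discharge_date) |>
    dplyr::group_by(.data$patient_id, .data$hospital_id) |>
    dplyr::mutate(
      prev_discharge = dplyr::lag(.data$discharge_date),
      new_admission = dplyr::row_number() == 1L |
        is.na(.data$prev_discharge) |
        .data$admit_date > .data$prev_discharge + gap_days,
      admission_seq = cumsum(.data$new_admission)
    ) |>
    dplyr::group_by(.data$patient_id, .data$hospital_id, .data$admission_seq) |>
    dplyr::summarise(
      admission_date = dplyr::first(.data$admit_date),
      discharge_date = dplyr::last(.data$discharge_date),
      destination = dplyr::last(.data$destination),
      prefecture = dplyr::first(.data$prefecture),
      diagnosis = dplyr::first(.data$diagnosis),
      sex = dplyr::first(.data$sex),
      age_group = dplyr::first(.data$age_group),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$admission_date >= as.Date(window_start),
                  .data$admission_date <= as.Date(window_end)) |>
    dplyr::mutate(
      discharged_community = !is.na(.data$destination) &
        .data$destination == "community",
      event_time = pmax(1L, days_between(.data$admission_date,
                                         .data$discharge_date))
    )
  pseudo
}

#' Prefecture-level indicators under either admission definition
#'
#' Computes, per prefecture: the number of admissions (overall, by age
#' group, and by diagnosis group) and the proportion discharged to the
#' community within one year. In `episode` mode the discharge proportion is
#' the Aalen-Johansen cumulative incidence at 360 days; in
#' `single_hospital` mode it is the crude within-hospital proportion of
#' pseudo-admissions discharged to the community within 360 days (transfers
#' out count as not discharged, mirroring what a facility survey can see).
#'
#' @param x Episode table (`mode = "episode"`) or pseudo-admission table
#'   from [single_hospital_view()] (`mode = "single_hospital"`).
#' @param mode One of `"episode"`, `"single_hospital"`.
#' @param horizon Days defining "within 1 year" (default 360).
#' @return A tidy tibble with `prefecture`, `indicator`
#'   (`admissions`, `admissions_age`, `admissions_diagnosis`,
#'   `discharge_proportion`), `level` (age/diagnosis level or `NA`), and
#'   `value`. Prefectures with no admissions keep a zero count row and a
#'   flagged (`NA`) proportion.
#' @export
prefecture_indicators <- function(x, mode = c("episode", "single_hospital"),
                                  horizon = 360) {
  mode <- match.arg(mode)
  prefs <- sort(unique(x$prefecture))

  counts <- x |>
    dplyr::count(.data$prefecture, name = "value") |>
    dplyr::mutate(indicator = "admissions", level = NA_character_)
  by_age <- x |>
    dplyr::count(.data$prefecture, level = as.character(.data$age_group),
                 name = "value") |>
    dplyr::mutate(indicator = "admissions_age")
  by_dx <- x |>
    dplyr::count(.data$prefecture, level = as.character(.data$diagnosis),
                 name = "value") |>
    dplyr::mutate(indicator = "admissions_diagnosis")

  prop <- purrr::map_dfr(prefs, function(p) {
    sub <- x[x$prefecture == p, ]
    value <- if (nrow(sub) == 0) {
      NA_real_
    } else if (mode == "episode") {
      fit <- aalen_johansen(sub$event_time, sub$outcome, variance = FALSE)
      cif_at(fit, "community", horizon)
    } else {
      mean(sub$discharged_community &
             !is.na(sub$event_time) & sub$event_time <= horizon)
    }
    tibble::tibble(prefecture = p, indicator = "discharge_proportion",
                   level = NA_character_, value = value)
  })

  dplyr::bind_rows(counts, by_age, by_dx, prop) |>
    dplyr::select("prefecture", "indicator", "level", "value") |>
    dplyr::arrange(.data$indicator, .data$level, .data$prefecture)
}

#' Pearson product-moment correlation with validation
#'
#' @param x,y Equal-length numeric vectors (length >= 3), neither constant.
#' @return The correlation coefficient in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Correlate prefecture indicators between the two admission definitions
#'
#' Joins episode-based and single-hospital indicator tables by prefecture,
#' indicator, and level, and reports the Pearson correlation across
#' prefectures for each indicator/level pair — the concordance summary of
#' how well a facility-survey style definition tracks the episode-based
#' one at prefecture level.
#'
#' @param episode_ind,single_ind Tables from [prefecture_indicators()].
#' @return A tibble with `indicator`, `level`, `n_prefectures`, and
#'   `correlation` (`NA` with a warning when undefined).
#' @export
indicator_correlations <- function(episode_ind, single_ind) {
  joined <- dplyr::inner_join(
    episode_ind, single_ind,
    by = c("prefecture", "indicator", "level"),
    suffix = c("_episode", "_single")
  ) |>
    dplyr::filter(!is.na(.data$value_episode), !is.na(.data$value_single))
  joined |>
    dplyr::group_by(.data$indicator, .data$level) |>
    dplyr::summarise(
      n_prefectures = dplyr::n(),
      correlation = tryCatch(
        pearson(.data$value_episode, .data$value_single),
        error = function(e) NA_real_),
      .groups = "drop"
    )
}
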