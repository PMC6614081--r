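#' Descriptive characteristics of the analysis cohort
#'
#' Counts and percentage shares of the cohort by route of admission, fee
#' category at admission, admission type, inter-hospital transfer, sex, age
#' group, and principal diagnosis group.
#'
#' @param episodes Classified episode table (see [build_episodes()]).
#' @return A tibble with `block`, `level`, `n`, `pct` (percent of the
#'   cohort; each block sums to 100 up to rounding).
#' @export
describe_cohort <- function(episodes) {
  blocks <- c(route = "route", fee_type = "fee_type",
              admission_type = "admission_type", transfer = "transfer",
              sex = "sex", age_group = "age_group", diagnosis = "diagnosis")
  blocks <- blocks[blocks %in% names(episodes)]
  purrr::map_dfr(blocks, function(col) {
    episodes |>
      dplyr::count(level = as.character(.data[[col]])) |>
      dplyr::mutate(block = col,
                    pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::select("block", "level", "n", "pct")
  })
}

#' Cumulative incidence of community discharge by stratum
#'
#' Runs the Aalen-Johansen estimator separately within each level of a
#' stratifying attribute (typically the fee category at admission) and
#' evaluates the chosen cause's cumulative incidence at a set of horizons.
#'
#' @param episodes Outcome-assigned episode table.
#' @param stratum Name of the stratifying column (default `"fee_type"`).
#' @param horizons Evaluation days (default 90/180/270/360).
#' @param cause Cause to report (default `"community"`).
#' @return A tibble with one row per stratum level: `n`, and one column
#'   `cif_<h>` per horizon (percent). Levels with no episodes are flagged
#'   with `empty = TRUE` and `NA` values.
#' @export
cif_by_stratum <- function(episodes, stratum = "fee_type",
                           horizons = c(90, 180, 270, 360),
                           cause = "community") {
  if (!stratum %in% names(episodes)) {
    stop("no column named `", stratum, "` in `episodes`", call. = FALSE)
  }
  levels <- sort(unique(as.character(episodes[[stratum]])))
  purrr::map_dfr(levels, function(lv) {
    sub <- episodes[episodes[[stratum]] == lv, ]
    row <- tibble::tibble("{stratum}" := lv, n = nrow(sub), empty = nrow(sub) == 0)
    vals <- if (nrow(sub) == 0) {
      rep(NA_real_, length(horizons))
    } else {
      fit <- aalen_johansen(sub$event_time, sub$outcome, variance = FALSE)
      100 * cif_at(fit, cause, horizons)
    }
    for (i in seq_along(horizons)) row[[paste0("cif_", horizons[i])]] <- vals[i]
    row
  })
}

#' Hospital-level discharge rates with rank groups
#'
#' For each fee category, computes every hospital's crude proportion of
#' episodes discharged to the community within `horizon` days, excludes
#' hospitals with fewer than `min_patients` episodes in that category
#' (estimates too uncertain), sorts the remaining hospitals by rate
#' (ascending, ties broken by hospital id) and partitions them into five
#' rank groups when at least 20 hospitals remain, otherwise three. Group
#' sizes differ by at most one; when the count is not divisible, the extra
#' hospitals go to the lowest-ranked groups. The crude proportion (rather
#' than a competing-risks estimate) is used because hospital-level rates
#' are conventionally reported as simple shares spanning 0-100%.
#'
#' @param episodes Outcome-assigned episode table (attributed to the
#'   admitting hospital).
#' @param horizon Days (default 90).
#' @param min_patients Minimum episodes per hospital-category cell
#'   (default 10).
#' @return An object of class `hospital_rate_table`: list with `hospitals`
#'   (per-hospital rates, eligibility and group assignment) and `groups`
#'   (per fee category and rank group: member count and rate range).
#' @export
hospital_rates <- function(episodes, horizon = 90, min_patients = 10) {
  rates <- episodes |>
    dplyr::group_by(.data$fee_type, .data$hospital_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_discharged = sum(.data$outcome == "community" &
                           .data$event_time <= horizon),
      rate = 100 * .data$n_discharged / .data$n,
      .groups = "drop"
    ) |>
    dplyr::mutate(eligible = .data$n >= min_patients)

  grouped <- rates |>
    dplyr::filter(.data$eligible) |>
    dplyr::group_by(.data$fee_type) |>
    dplyr::arrange(.data$rate, .data$hospital_id, .by_group = TRUE) |>
    dplyr::mutate(rank_group = rank_groups(dplyr::n())) |>
    dplyr::ungroup()

  hospitals <- rates |>
    dplyr::left_join(dplyr::select(grouped, "fee_type", "hospital_id",
                                   "rank_group"),
                     by = c("fee_type", "hospital_id")) |>
    dplyr::arrange(.data$fee_type, .data$rate, .data$hospital_id)

  groups <- if (nrow(grouped) == 0) {
    tibble::tibble(fee_type = character(0), rank_group = integer(0),
                   n_hospitals = integer(0), rate_min = double(0),
                   rate_max = double(0))
  } else {
    grouped |>
      dplyr::group_by(.data$fee_type, .data$rank_group) |>
      dplyr::summarise(n_hospitals = dplyr::n(),
                       rate_min = min(.data$rate),
                       rate_max = max(.data$rate),
                       .groups = "drop")
  }

  summary <- rates |>
    dplyr::group_by(.data$fee_type) |>
    dplyr::summarise(n_hospitals = dplyr::n(),
                     n_eligible = sum(.data$eligible),
                     .groups = "drop")

  structure(list(hospitals = hospitals, groups = groups, summary = summary,
                 horizon = horizon, min_patients = min_patients),
            class = "hospital_rate_table")
}

# Rank-group labels for n hospitals already sorted ascending by rate:
# five groups for n >= 20, three below; sizes differ by <= 1 with the
# remainder allocated to the lowest-ranked groups.
rank_groups <- function(n) {
  g <- if (n >= 20) 5L else 3L
  base <- n %/% g
  extra <- n %% g
  sizes <- rep(base, g) + (seq_len(g) <= extra)
  rep(seq_len(g), times = sizes)
}

#' @export
print.hospital_rate_table <- function(x, ...) {
  cat(sprintf("<hospital_rate_table> %d-day community discharge, hospitals with >= %d patients\n",
              x$horizon, x$min_patients))
  print(x$summary, n = Inf)
  invisible(x)
}
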