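#' Link per-hospital stay records into admission episodes
#'
#' A single episode of psychiatric admission runs from the date of
#' admission to a psychiatric ward (from the community or a general ward)
#' to the date of discharge to the community, a general ward, or death.
#' Claims fragment such an episode into one row per hospital: a transfer is
#' encoded as a discharge with destination `other_hospital` followed by an
#' admission elsewhere on the same (or next) calendar day. This function
#' re-chains them: two stays of one patient belong to the same episode iff
#' the next admission date is at most `gap_days` after the previous
#' discharge date.
#'
#' @param stays Stay table (columns as written by [emit_claims()]).
#' @param gap_days Maximum gap, in days, between a discharge and the next
#'   admission for the two stays to be chained (default 1: same-day or
#'   next-day re-admission is a transfer).
#' @return A tibble of episodes (outcome fields unset; see
#'   [assign_outcome()]): admission date, last discharge date (`NA` while
#'   still hospitalized), final destination, `transfer` flag (episode spans
#'   two or more hospitals), fee type / hospital / prefecture / legal type
#'   of the first segment, any-segment ECT flag, and segment count. The
#'   segment-level table (with `episode_id`) is attached as attribute
#'   `"segments"` and can be retrieved with [episode_segments()].
#' @export
link_segments <- function(stays, gap_days = 1L) {
  validate_stays(stays)
  if (gap_days < 0) stop("`gap_days` must be >= 0", call. = FALSE)

  seg <- stays |>
    dplyr::arrange(.data$patient_id, .data$admit_date,
                   is.na(.data$discharge_date), .data$discharge_date) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(
      prev_discharge = dplyr::lag(.data$discharge_date),
      new_episode = dplyr::row_number() == 1L |
        is.na(.data$prev_discharge) |
        .data$admit_date > .data$prev_discharge + gap_days,
      episode_seq = cumsum(.data$new_episode)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(episode_id = paste0(.data$patient_id, "#", .data$episode_seq))

  episodes <- seg |>
    dplyr::group_by(.data$patient_id, .data$episode_id) |>
    dplyr::summarise(
      admission_date = dplyr::first(.data$admit_date),
      last_discharge_date = dplyr::last(.data$discharge_date),
      final_destination = dplyr::last(.data$destination),
      transfer = dplyr::n_distinct(.data$hospital_id) > 1L,
      fee_type = dplyr::first(.data$fee_code),
      hospital_id = dplyr::first(.data$hospital_id),
      prefecture = dplyr::first(.data$prefecture),
      legal_type = dplyr::first(.data$legal_type),
      ect_any = any(.data$ect),
      diagnosis = dplyr::first(.data$diagnosis),
      sex = dplyr::first(.data$sex),
      age_group = dplyr::first(.data$age_group),
      n_segments = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$patient_id, .data$admission_date)

  structure(episodes,
            segments = dplyr::select(seg, -"prev_discharge", -"new_episode",
                                     -"episode_seq"))
}

#' @rdname link_segments
#' @param episodes An episode table produced by [link_segments()].
#' @export
episode_segments <- function(episodes) {
  seg <- attr(episodes, "segments")
  if (is.null(seg)) stop("no segment table attached; was this built by link_segments()?",
                         call. = FALSE)
  seg
}

validate_stays <- function(stays) {
  needed <- c("patient_id", "hospital_id", "fee_code", "admit_date",
              "discharge_date", "destination")
  missing <- setdiff(needed, names(stays))
  if (length(missing)) {
    stop("stay table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.na(stays$discharge_date) &
                 stays$discharge_date < stays$admit_date)
  if (length(bad)) {
    stop(sprintf("data-validation error: discharge before admission in stay row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  bad_dest <- which(is.na(stays$discharge_date) != is.na(stays$destination))
  if (length(bad_dest)) {
    stop(sprintf("data-validation error: destination must be present iff discharge date is, row(s) %s",
                 paste(utils::head(bad_dest, 5), collapse = ", ")), call. = FALSE)
  }
  invisible(stays)
}

#' Apply the new-admission cohort rules
#'
#' Sequentially removes, with full accounting:
#' \enumerate{
#'   \item \strong{same-day multi-hospital patients}: any patient with two
#'     stays at different hospitals overlapping by more than a shared
#'     boundary day loses all episodes (identification-code errors; a
#'     legitimate transfer only touches at the discharge/admission day);
#'   \item \strong{prevalent admissions}: episodes admitted before
#'     `window_start` and still in the ward at `window_start`;
#'   \item \strong{out-of-window admissions}: episodes admitted outside
#'     `[window_start, window_end]`;
#'   \item \strong{enrollment-unverified admissions}: episodes whose patient
#'     has neither an enrollment marker in a month strictly before the
#'     admission month nor any earlier claim, so enrollment at least one
#'     day before admission cannot be confirmed.
#' }
#'
#' @param episodes Episode table from [link_segments()].
#' @param enrollment Patient-month enrollment markers (columns
#'   `patient_id`, `month`).
#' @param window_start,window_end Study admission window.
#' @return A list: `episodes` (the retained subset, segments attribute
#'   preserved) and `log` (a `cohort_filter_log` tibble with one row per
#'   rule plus the retained count; removed + retained = input).
#' @export
apply_cohort_filters <- function(episodes, enrollment,
                                 window_start = as.Date("2014-04-01"),
                                 window_end = as.Date("2016-03-31")) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  seg <- attr(episodes, "segments")
  n_in <- nrow(episodes)
  if (n_in == 0) {
    log <- tibble::tibble(
      rule = c("same_day_multi_hospital", "prevalent_at_window_start",
               "out_of_window", "enrollment_unverified"),
      removed = 0L)
    return(list(episodes = episodes,
                log = structure(dplyr::bind_rows(
                  log, tibble::tibble(rule = "retained", removed = 0L)),
                  class = c("cohort_filter_log", class(log)))))
  }

  # 1. patients hospitalized in two hospitals at once (id-code errors)
  bad_patients <- if (is.null(seg)) character(0) else overlapping_patients(seg)
  is_bad <- episodes$patient_id %in% bad_patients
  n_same_day <- sum(is_bad)
  episodes_1 <- episodes[!is_bad, ]

  # 2. prevalent at window start: admitted before, still in ward at start
  still_in <- is.na(episodes_1$last_discharge_date) |
    episodes_1$last_discharge_date >= window_start
  prevalent <- episodes_1$admission_date < window_start & still_in
  n_prevalent <- sum(prevalent)
  episodes_2 <- episodes_1[!prevalent, ]

  # 3. admissions outside the study window
  out_win <- episodes_2$admission_date < window_start |
    episodes_2$admission_date > window_end
  n_out <- sum(out_win)
  episodes_3 <- episodes_2[!out_win, ]

  # 4. enrollment verified by a marker month strictly before the admission
  #    month, or by any earlier claim of the same patient
  first_marker <- if (nrow(enrollment) == 0) {
    tibble::tibble(patient_id = character(0), first_month = as.Date(character(0)))
  } else {
    enrollment |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(first_month = min(.data$month), .groups = "drop")
  }
  first_claim <- if (is.null(seg)) {
    episodes |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(first_claim = min(.data$admission_date), .groups = "drop")
  } else {
    seg |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(first_claim = min(.data$admit_date), .groups = "drop")
  }
  episodes_4 <- episodes_3 |>
    dplyr::left_join(first_marker, by = "patient_id") |>
    dplyr::left_join(first_claim, by = "patient_id") |>
    dplyr::mutate(verified =
                    (!is.na(.data$first_month) &
                       .data$first_month < month_floor(.data$admission_date)) |
                    (!is.na(.data$first_claim) &
                       .data$first_claim < .data$admission_date))
  n_unverified <- sum(!episodes_4$verified)
  kept <- episodes_4 |>
    dplyr::filter(.data$verified) |>
    dplyr::select(-"first_month", -"first_claim", -"verified")

  if (!is.null(seg)) {
    attr(kept, "segments") <- seg[seg$episode_id %in% kept$episode_id, ]
  }
  log <- tibble::tibble(
    rule = c("same_day_multi_hospital", "prevalent_at_window_start",
             "out_of_window", "enrollment_unverified", "retained"),
    removed = c(n_same_day, n_prevalent, n_out, n_unverified, nrow(kept))
  )
  list(episodes = kept,
       log = structure(log, class = c("cohort_filter_log", class(log))))
}

# Patients with stays at different hospitals overlapping by more than a
# boundary touch (strict interval overlap). Open stays count as extending
# indefinitely.
overlapping_patients <- function(seg) {
  multi <- seg |>
    dplyr::count(.data$patient_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi) == 0) return(character(0))
  s <- seg |>
    dplyr::semi_join(multi, by = "patient_id") |>
    dplyr::mutate(end = dplyr::if_else(is.na(.data$discharge_date),
                                       as.Date("9999-12-31"),
                                       .data$discharge_date)) |>
    dplyr::arrange(.data$patient_id, .data$admit_date, .data$end)
  bad <- s |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(
      running_end = dplyr::lag(cummax(as.integer(.data$end))),
      prev_hospital = dplyr::lag(.data$hospital_id),
      clash = !is.na(.data$running_end) &
        as.integer(.data$admit_date) < .data$running_end &
        .data$hospital_id != .data$prev_hospital
    ) |>
    dplyr::summarise(any_clash = any(.data$clash), .groups = "drop")
  bad$patient_id[bad$any_clash]
}

#' Assign outcome and event time under dual administrative censoring
#'
#' Follow-up ends at the earlier of `observation_end` and `max_days` after
#' admission. An episode whose final destination (community, general ward,
#' or death) occurs on or before that boundary gets that outcome at its
#' event time; otherwise it is censored at the boundary. Event time is the
#' day difference between end and admission, floored at 1 (a same-day
#' discharge counts as a one-day stay).
#'
#' @param episodes Episode table from [link_segments()] (filtered or not).
#' @param observation_end Administrative end of observation (default
#'   2016-09-30).
#' @param max_days Maximum follow-up after admission (default 365).
#' @return The episode table with `outcome` (community / general_ward /
#'   death / censored) and `event_time` (days) columns.
#' @export
assign_outcome <- function(episodes,
                           observation_end = as.Date("2016-09-30"),
                           max_days = 365L) {
  observation_end <- as.Date(observation_end)
  unresolved <- !is.na(episodes$final_destination) &
    episodes$final_destination == "other_hospital"
  if (any(unresolved)) {
    stop(sprintf("data-validation error: unterminated transfer chain (final destination other_hospital) for episode(s) %s",
                 paste(utils::head(episodes$episode_id[unresolved], 5),
                       collapse = ", ")), call. = FALSE)
  }
  censor_date <- pmin(observation_end, episodes$admission_date + max_days)
  has_event <- !is.na(episodes$last_discharge_date) &
    !is.na(episodes$final_destination) &
    episodes$last_discharge_date <= censor_date
  out <- episodes
  out$outcome <- ifelse(has_event, episodes$final_destination, "censored")
  end <- dplyr::if_else(has_event, episodes$last_discharge_date, censor_date)
  out$event_time <- pmax(1L, days_between(episodes$admission_date, end))
  attr(out, "segments") <- attr(episodes, "segments")
  out
}

#' Classify the admission type of an episode
#'
#' A planned admission is operationally defined as use of
#' electroconvulsive therapy with a length of stay of at most 3 days;
#' anything else keeps the legal admission-type flag (voluntary or
#' involuntary) of the first segment.
#'
#' @param episodes Episode table with `event_time` set (see
#'   [assign_outcome()]).
#' @return The table with an `admission_type` column.
#' @export
classify_admission <- function(episodes) {
  if (!"event_time" %in% names(episodes)) {
    stop("`episodes` needs an `event_time` column; run assign_outcome() first",
         call. = FALSE)
  }
  out <- episodes
  out$admission_type <- ifelse(episodes$ect_any & episodes$event_time <= 3,
                               "planned", episodes$legal_type)
  attr(out, "segments") <- attr(episodes, "segments")
  out
}

#' Classify the route of admission
#'
#' An episode is admitted from a general ward iff the same patient has a
#' general-ward stay ending on the admission date or the day before;
#' otherwise the route is the community (home or institution).
#'
#' @param episodes Episode table.
#' @param general_ward_stays General-ward stay table (columns `patient_id`,
#'   `discharge_date`).
#' @return The table with a `route` column.
#' @export
classify_route <- function(episodes, general_ward_stays) {
  gw <- general_ward_stays |>
    dplyr::filter(!is.na(.data$discharge_date)) |>
    dplyr::select("patient_id", gw_end = "discharge_date")
  hit <- episodes |>
    dplyr::select("episode_id", "patient_id", "admission_date") |>
    dplyr::inner_join(gw, by = "patient_id",
                      relationship = "many-to-many") |>
    dplyr::filter(as.numeric(.data$admission_date - .data$gw_end) %in% c(0, 1)) |>
    dplyr::distinct(.data$episode_id)
  out <- episodes
  out$route <- ifelse(episodes$episode_id %in% hit$episode_id,
                      "general_ward", "community")
  attr(out, "segments") <- attr(episodes, "segments")
  out
}

#' Build the analysis cohort from raw claims in one call
#'
#' Convenience wrapper chaining [link_segments()],
#' [apply_cohort_filters()], [assign_outcome()], [classify_admission()],
#' and [classify_route()].
#'
#' @param bundle A `claims_bundle` (from [emit_claims()] or
#'   [read_claims()]).
#' @param gap_days Transfer-chaining tolerance in days (default 1).
#' @param window_start,window_end Study admission window.
#' @param observation_end Administrative censoring date.
#' @param max_days Maximum follow-up after admission (default 365).
#' @return A list: `episodes` (fully classified, outcome-assigned) and
#'   `filter_log`.
#' @export
build_episodes <- function(bundle,
                           gap_days = 1L,
                           window_start = as.Date("2014-04-01"),
                           window_end = as.Date("2016-03-31"),
                           observation_end = as.Date("2016-09-30"),
                           max_days = 365L) {
  linked <- link_segments(bundle$stays, gap_days = gap_days)
  filtered <- apply_cohort_filters(linked, bundle$enrollment,
                                   window_start = window_start,
                                   window_end = window_end)
  ep <- filtered$episodes |>
    assign_outcome(observation_end = observation_end, max_days = max_days) |>
    classify_admission() |>
    classify_route(bundle$general_ward)
  list(episodes = ep, filter_log = filtered$log)
}
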