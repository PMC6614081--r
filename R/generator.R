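#' Generate a latent cohort of psychiatric admission episodes
#'
#' Draws the ground-truth cohort the synthetic claims are later fragmented
#' from: one admission episode per patient, with admission date, latent
#' event time and cause, fee category, admission type, route, demographics,
#' and an optional inter-hospital transfer schedule.
#'
#' Admission dates follow a log-linear seasonal intensity
#' `exp(A * cos(2*pi*(m - peak_month)/12))` over the calendar months of the
#' study window (day uniform within month). Event times are drawn from the
#' fee category's piecewise-constant cause-specific hazards and recorded in
#' whole days (ceiling, minimum 1). Planned admissions (electroconvulsive
#' therapy, stay of at most 3 days) are drawn as a separate point mass with
#' a uniform 1-3 day stay and community discharge. Each stochastic concern
#' draws under its own named random stream derived from `config$seed`, so
#' toggling one feature leaves the others' draws unchanged.
#'
#' @param config A [generator_config()].
#' @return A tibble of latent episodes with one row per patient, including
#'   the latent `event_day` and `cause` (`NA` cause when the total hazard is
#'   exhausted before any event), the transfer schedule (`transfer_day`,
#'   offset in days from admission, 0 = same-day transfer), and the
#'   admitting/receiving hospitals.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop("`config` must be a generator_config", call. = FALSE)
  }
  n <- config$n_patients
  seed <- config$seed

  # Admission dates: seasonal month weights, then uniform day within month.
  months <- month_seq(config$window_start, config$window_end)
  m_idx <- as.integer(format(months, "%m"))
  weight <- exp(config$seasonal_amplitude *
                  cos(2 * pi * (m_idx - config$peak_month) / 12))
  admission_date <- with_stream(seed, "dates", {
    mo <- sample(length(months), n, replace = TRUE, prob = weight)
    day <- floor(stats::runif(n) * vapply(months[mo], days_in_month, integer(1)))
    months[mo] + day
  })

  fee_type <- with_stream(seed, "fee", {
    sample(names(config$fee_type_mix), n, replace = TRUE,
           prob = config$fee_type_mix)
  })

  admission_type <- with_stream(seed, "admission_type", {
    sample(names(config$admission_type_probs), n, replace = TRUE,
           prob = config$admission_type_probs)
  })
  planned <- admission_type == "planned"
  # Legal (voluntary/involuntary) flag carried by the claims rows; a planned
  # episode is booked as voluntary and re-derived downstream from ECT + LOS.
  legal_type <- ifelse(planned, "voluntary", admission_type)

  events <- with_stream(seed, "causes", {
    time <- rep(Inf, n)
    cause <- rep(NA_character_, n)
    for (ft in unique(fee_type)) {
      sel <- which(fee_type == ft)
      ev <- sample_piecewise_events(length(sel), config$cause_hazards[[ft]])
      time[sel] <- ev$time
      cause[sel] <- ev$cause
    }
    list(time = time, cause = cause)
  })
  event_day <- ifelse(is.finite(events$time), pmax(1, ceiling(events$time)), Inf)
  cause <- events$cause

  with_stream(seed, "planned_stay", {
    event_day[planned] <- sample(1:3, sum(planned), replace = TRUE)
    cause[planned] <- "community"
  })

  ect <- planned
  with_stream(seed, "ect", {
    # Background ECT only where LOS > 3 d, so the planned classification
    # rule cannot re-label a non-planned episode.
    eligible <- !planned & event_day > 3
    ect[eligible] <- stats::runif(sum(eligible)) < config$ect_background_rate
  })

  transfer <- with_stream(seed, "transfer", {
    stats::runif(n) < config$transfer_prob
  })
  transfer_day <- rep(NA_integer_, n)
  with_stream(seed, "transfer_timing", {
    span <- ifelse(is.finite(event_day), event_day, 365)
    transfer_day[transfer] <-
      as.integer(floor(stats::runif(sum(transfer)) * span[transfer]))
  })

  hosp <- with_stream(seed, "hospital", {
    h1 <- sample.int(config$n_hospitals, n, replace = TRUE)
    # receiving hospital differs from the admitting one
    h2 <- sample.int(config$n_hospitals - 1L, n, replace = TRUE)
    h2 <- ifelse(h2 >= h1, h2 + 1L, h2)
    list(h1 = h1, h2 = h2)
  })

  fee_type_2 <- with_stream(seed, "fee_after_transfer", {
    sample(names(config$fee_type_mix), n, replace = TRUE,
           prob = config$fee_type_mix)
  })

  demo <- with_stream(seed, "demographics", {
    list(
      sex = sample(names(config$sex_probs), n, TRUE, config$sex_probs),
      age = sample(names(config$age_probs), n, TRUE, config$age_probs),
      dx = sample(names(config$diagnosis_probs), n, TRUE, config$diagnosis_probs)
    )
  })
  route <- with_stream(seed, "route", {
    sample(names(config$route_probs), n, TRUE, config$route_probs)
  })

  tibble::tibble(
    patient_id = sprintf("P%07d", seq_len(n)),
    admission_date = admission_date,
    event_day = event_day,
    cause = cause,
    fee_type = fee_type,
    admission_type = admission_type,
    legal_type = legal_type,
    ect = ect,
    route = route,
    diagnosis = demo$dx,
    sex = demo$sex,
    age_group = demo$age,
    transfer = transfer,
    transfer_day = transfer_day,
    hospital_id = sprintf("H%04d", hosp$h1),
    transfer_hospital_id = ifelse(transfer, sprintf("H%04d", hosp$h2), NA_character_),
    prefecture = hospital_prefecture(hosp$h1, config$n_prefectures),
    transfer_fee_type = ifelse(transfer, fee_type_2, NA_character_)
  )
}

hospital_prefecture <- function(hospital_index, n_prefectures) {
  ((hospital_index - 1L) %% n_prefectures) + 1L
}

#' Fragment latent episodes into per-hospital claims rows
#'
#' Inverts the episode linkage: each latent episode with a transfer yields
#' one stay row per hospital segment, contiguous in time (the receiving
#' hospital admits on the calendar day the sending one discharges, which is
#' how claims encode transfers), with destination code `other_hospital` on
#' every segment but the last. Stays still open at the observation end have
#' no discharge date and no destination. A `public_fund_frac` share of
#' episodes is silently withheld (claims solely covered by public funds
#' never reach a claims database). Monthly enrollment markers are emitted
#' for every emitted patient from two months before admission through the
#' end of the stay, and patients admitted from a general ward get a
#' general-ward stay ending on the admission date. `prevalent_frac` extra
#' patients carry a psychiatric stay straddling the window start.
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param config The same [generator_config()].
#' @return A list of class `claims_bundle`: `stays`, `enrollment`
#'   (patient-month markers), `general_ward` (pre-admission general-ward
#'   stays). The ids of withheld patients are kept in attribute
#'   `"withheld"`.
#' @export
emit_claims <- function(cohort, config) {
  keep <- with_stream(config$seed, "withholding", {
    stats::runif(nrow(cohort)) >= config$public_fund_frac
  })
  withheld <- cohort$patient_id[!keep]
  co <- cohort[keep, ]
  obs_end <- config$observation_end

  end_date <- co$admission_date + ifelse(is.finite(co$event_day), co$event_day, NA)
  observed_end <- !is.na(end_date) & end_date <= obs_end
  transfer_date <- co$admission_date + co$transfer_day
  has_seg2 <- !is.na(transfer_date) & transfer_date <= obs_end

  first_seg <- tibble::tibble(
    patient_id = co$patient_id,
    hospital_id = co$hospital_id,
    prefecture = co$prefecture,
    fee_code = co$fee_type,
    admit_date = co$admission_date,
    discharge_date = dplyr::case_when(
      has_seg2 ~ transfer_date,
      observed_end ~ end_date,
      TRUE ~ as.Date(NA)
    ),
    destination = dplyr::case_when(
      has_seg2 ~ "other_hospital",
      observed_end ~ co$cause,
      TRUE ~ NA_character_
    ),
    legal_type = co$legal_type,
    ect = co$ect,
    diagnosis = co$diagnosis,
    sex = co$sex,
    age_group = co$age_group
  )

  seg2 <- tibble::tibble(
    patient_id = co$patient_id[has_seg2],
    hospital_id = co$transfer_hospital_id[has_seg2],
    prefecture = hospital_prefecture(
      as.integer(sub("^H", "", co$transfer_hospital_id[has_seg2])),
      config$n_prefectures),
    fee_code = co$transfer_fee_type[has_seg2],
    admit_date = transfer_date[has_seg2],
    discharge_date = dplyr::if_else(observed_end[has_seg2],
                                    end_date[has_seg2], as.Date(NA)),
    destination = dplyr::if_else(observed_end[has_seg2],
                                 co$cause[has_seg2], NA_character_),
    legal_type = co$legal_type[has_seg2],
    ect = FALSE,
    diagnosis = co$diagnosis[has_seg2],
    sex = co$sex[has_seg2],
    age_group = co$age_group[has_seg2]
  )

  stays <- dplyr::bind_rows(first_seg, seg2)

  # Prevalent patients: already in a psychiatric ward at window start.
  n_prev <- round(config$prevalent_frac * config$n_patients)
  if (n_prev > 0) {
    prev <- with_stream(config$seed, "prevalent", {
      h <- sample.int(config$n_hospitals, n_prev, replace = TRUE)
      tibble::tibble(
        patient_id = sprintf("Q%07d", seq_len(n_prev)),
        hospital_id = sprintf("H%04d", h),
        prefecture = hospital_prefecture(h, config$n_prefectures),
        fee_code = sample(names(config$fee_type_mix), n_prev, TRUE,
                          config$fee_type_mix),
        admit_date = config$window_start -
          as.integer(floor(stats::runif(n_prev, 30, 365))),
        discharge_date = config$window_start +
          as.integer(floor(stats::runif(n_prev, 0, 180))),
        destination = "community",
        legal_type = sample(c("voluntary", "involuntary"), n_prev, TRUE,
                            prob = c(0.65, 0.35)),
        ect = FALSE,
        diagnosis = sample(names(config$diagnosis_probs), n_prev, TRUE,
                           config$diagnosis_probs),
        sex = sample(names(config$sex_probs), n_prev, TRUE, config$sex_probs),
        age_group = sample(names(config$age_probs), n_prev, TRUE,
                           config$age_probs)
      )
    })
    stays <- dplyr::bind_rows(stays, prev)
  }
  stays <- dplyr::arrange(stays, .data$patient_id, .data$admit_date,
                          .data$discharge_date)

  # Monthly enrollment markers: two months before first admission through
  # the end of the stay (or the observation end while still hospitalized).
  enr_src <- stays |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      first = min(.data$admit_date),
      last = if (anyNA(.data$discharge_date)) obs_end else max(.data$discharge_date),
      .groups = "drop"
    )
  enrollment <- enr_src |>
    dplyr::mutate(month = purrr::map2(.data$first, .data$last, function(f, l) {
      month_seq(f - 62, min(l, obs_end))
    })) |>
    dplyr::select("patient_id", "month") |>
    tidyr::unnest("month")

  gw_sel <- co$route == "general_ward"
  general_ward <- with_stream(config$seed, "general_ward_stays", {
    len <- as.integer(floor(stats::runif(sum(gw_sel), 3, 31)))
    tibble::tibble(
      patient_id = co$patient_id[gw_sel],
      hospital_id = co$hospital_id[gw_sel],
      admit_date = co$admission_date[gw_sel] - len,
      discharge_date = co$admission_date[gw_sel]
    )
  })

  structure(
    list(stays = stays, enrollment = enrollment, general_ward = general_ward),
    withheld = withheld,
    class = "claims_bundle"
  )
}

#' Merge patient identifiers to emulate identification-code errors
#'
#' Real claims identifiers are hashed from insurance numbers and
#' demographics; hash collisions merge distinct patients into one pseudo-id,
#' which surfaces downstream as one "patient" hospitalized in two hospitals
#' on the same day. This injector merges a sampled fraction of patient-id
#' pairs so the cohort filters can be exercised.
#'
#' @param stays Stay table (as in a `claims_bundle`).
#' @param collision_rate Fraction of patients that end up sharing an id
#'   with another patient (each merged pair contributes two such patients).
#' @param seed Integer seed.
#' @return The stay table with merged `patient_id`s; attribute
#'   `"merged_ids"` maps old to new ids.
#' @export
inject_id_errors <- function(stays, collision_rate, seed = 1L) {
  if (!is.numeric(collision_rate) || collision_rate < 0 || collision_rate > 1) {
    stop("configuration error in `collision_rate`: must be in [0, 1]", call. = FALSE)
  }
  if (collision_rate == 0) return(stays)
  ids <- unique(stays$patient_id)
  n_pairs <- round(collision_rate * length(ids) / 2)
  if (n_pairs == 0) return(stays)
  picked <- with_stream(seed, "id_errors", sample(ids, 2L * n_pairs))
  absorbed <- picked[seq_len(n_pairs) * 2L]
  survivor <- picked[seq_len(n_pairs) * 2L - 1L]
  map <- stats::setNames(survivor, absorbed)
  hit <- stays$patient_id %in% absorbed
  stays$patient_id[hit] <- unname(map[stays$patient_id[hit]])
  attr(stays, "merged_ids") <- tibble::tibble(absorbed = absorbed,
                                              survivor = survivor)
  stays
}

#' Write or read a claims bundle as delimited text files
#'
#' Writes `stays.csv`, `enrollment.csv`, and `general_ward.csv` (UTF-8,
#' header row, ISO-8601 dates) into `dir`; optionally the latent episode
#' truth as `latent_episodes.csv` (testing only, a real claims extract has
#' no such file).
#'
#' @param bundle A `claims_bundle` from [emit_claims()].
#' @param dir Output directory (created if missing).
#' @param latent Optional latent cohort tibble from [generate_cohort()].
#' @return `read_claims()` returns a `claims_bundle`.
#' @export
write_claims <- function(bundle, dir, latent = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(bundle$stays, file.path(dir, "stays.csv"), na = "")
  readr::write_csv(bundle$enrollment, file.path(dir, "enrollment.csv"), na = "")
  readr::write_csv(bundle$general_ward, file.path(dir, "general_ward.csv"), na = "")
  if (!is.null(latent)) {
    readr::write_csv(latent, file.path(dir, "latent_episodes.csv"), na = "")
  }
  invisible(dir)
}

#' @rdname write_claims
#' @export
read_claims <- function(dir) {
  stays <- readr::read_csv(
    file.path(dir, "stays.csv"), na = "",
    col_types = readr::cols(
      patient_id = "c", hospital_id = "c", prefecture = "i", fee_code = "c",
      admit_date = readr::col_date(), discharge_date = readr::col_date(),
      destination = "c", legal_type = "c", ect = "l", diagnosis = "c",
      sex = "c", age_group = "c"
    )
  )
  enrollment <- readr::read_csv(
    file.path(dir, "enrollment.csv"), na = "",
    col_types = readr::cols(patient_id = "c", month = readr::col_date())
  )
  general_ward <- readr::read_csv(
    file.path(dir, "general_ward.csv"), na = "",
    col_types = readr::cols(
      patient_id = "c", hospital_id = "c",
      admit_date = readr::col_date(), discharge_date = readr::col_date()
    )
  )
  structure(list(stays = stays, enrollment = enrollment,
                 general_ward = general_ward),
            class = "claims_bundle")
}
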