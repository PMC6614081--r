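#' Configuration for the synthetic claims generator
#'
#' Builds and validates the parameter set controlling the synthetic
#' claims generator. Defaults emulate the Japanese national claims cohort of
#' new psychiatric admissions in fiscal years 2014-2015: a two-year
#' admission window with monthly seasonality peaking in July, the national
#' fee-category mix, per-category piecewise-constant discharge hazards
#' calibrated to published cumulative incidences (see
#' [fee_type_profiles()]), a 2.6% inter-hospital transfer prevalence,
#' admission-type shares of 64.4/35.1/0.5% (voluntary/involuntary/planned),
#' and an 85.3/14.7% community/general-ward route split.
#'
#' @param n_patients Number of latent admission episodes (one per patient).
#' @param n_hospitals Number of hospitals; each is assigned a prefecture by
#'   cycling through `1..n_prefectures`.
#' @param n_prefectures Number of prefectures (default 47).
#' @param window_start,window_end Study admission window (defaults fiscal
#'   2014-2015: 2014-04-01 to 2016-03-31).
#' @param observation_end Administrative end of claims observation
#'   (default 2016-09-30).
#' @param fee_type_mix Named probability vector over fee-category codes.
#' @param cause_hazards Named list (one entry per fee category in
#'   `fee_type_mix`) of hazard matrices as returned by
#'   [calibrate_hazards()]. Defaults are calibrated per category to the
#'   published cumulative-incidence profiles, adjusting for the planned
#'   short-stay point mass.
#' @param transfer_prob Probability an episode contains an inter-hospital
#'   transfer (default 0.026).
#' @param admission_type_probs Named probabilities for voluntary,
#'   involuntary, planned.
#' @param route_probs Named probabilities for admission route community /
#'   general_ward.
#' @param sex_probs,age_probs,diagnosis_probs Demographic mixes; defaults
#'   are the published cohort shares.
#' @param seasonal_amplitude Relative amplitude of the log-linear monthly
#'   admission intensity (0 = flat). Default 0.1, a modest ~±10% seasonal
#'   swing consistent with a visible summer peak.
#' @param peak_month Calendar month (1-12) of peak admission intensity
#'   (default 7, July).
#' @param public_fund_frac Fraction of latent episodes withheld from the
#'   emitted claims, emulating claims solely covered by public funds that a
#'   claims database never sees (default 0; the national database gap is
#'   about 0.19).
#' @param prevalent_frac Additional patients (as a fraction of
#'   `n_patients`) already hospitalized at `window_start`; they carry a
#'   stay straddling the window start and must be excluded downstream.
#' @param ect_background_rate Rate of electroconvulsive-therapy claims among
#'   non-planned episodes staying more than 3 days (default 0.02).
#' @param seed Integer seed; all generator randomness derives from it via
#'   independent named streams.
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_patients = 10000,
                             n_hospitals = 150,
                             n_prefectures = 47,
                             window_start = as.Date("2014-04-01"),
                             window_end = as.Date("2016-03-31"),
                             observation_end = as.Date("2016-09-30"),
                             fee_type_mix = NULL,
                             cause_hazards = NULL,
                             transfer_prob = 0.026,
                             admission_type_probs = c(voluntary = 0.644,
                                                      involuntary = 0.351,
                                                      planned = 0.005),
                             route_probs = c(community = 0.853,
                                             general_ward = 0.147),
                             sex_probs = NULL,
                             age_probs = NULL,
                             diagnosis_probs = NULL,
                             seasonal_amplitude = 0.1,
                             peak_month = 7,
                             public_fund_frac = 0,
                             prevalent_frac = 0,
                             ect_background_rate = 0.02,
                             seed = 1L) {
  demo <- default_demographics()
  profiles <- fee_type_profiles()

  if (is.null(fee_type_mix)) {
    fee_type_mix <- stats::setNames(profiles$share, profiles$fee_type)
  }
  sex_probs <- sex_probs %||% demo$sex_probs
  age_probs <- age_probs %||% demo$age_probs
  diagnosis_probs <- diagnosis_probs %||% demo$diagnosis_probs

  cfg <- list(
    n_patients = assert_count(n_patients, "n_patients"),
    n_hospitals = assert_count(n_hospitals, "n_hospitals"),
    n_prefectures = assert_count(n_prefectures, "n_prefectures"),
    window_start = as.Date(window_start),
    window_end = as.Date(window_end),
    observation_end = as.Date(observation_end),
    fee_type_mix = assert_prob_vector(fee_type_mix, "fee_type_mix"),
    transfer_prob = assert_fraction(transfer_prob, "transfer_prob"),
    admission_type_probs = assert_prob_vector(admission_type_probs, "admission_type_probs"),
    route_probs = assert_prob_vector(route_probs, "route_probs"),
    sex_probs = assert_prob_vector(sex_probs, "sex_probs"),
    age_probs = assert_prob_vector(age_probs, "age_probs"),
    diagnosis_probs = assert_prob_vector(diagnosis_probs, "diagnosis_probs"),
    seasonal_amplitude = seasonal_amplitude,
    peak_month = peak_month,
    public_fund_frac = assert_fraction(public_fund_frac, "public_fund_frac"),
    prevalent_frac = assert_fraction(prevalent_frac, "prevalent_frac"),
    ect_background_rate = assert_fraction(ect_background_rate, "ect_background_rate"),
    seed = assert_count(seed, "seed", min = 0L)
  )

  if (cfg$window_end <= cfg$window_start) {
    stop("configuration error in `window_end`: must be after `window_start`",
         call. = FALSE)
  }
  if (cfg$observation_end < cfg$window_end) {
    stop("configuration error in `observation_end`: must be on or after `window_end`",
         call. = FALSE)
  }
  if (!is.numeric(seasonal_amplitude) || seasonal_amplitude < 0) {
    stop("configuration error in `seasonal_amplitude`: must be >= 0", call. = FALSE)
  }
  if (!peak_month %in% 1:12) {
    stop("configuration error in `peak_month`: must be in 1..12", call. = FALSE)
  }
  if (!all(c("voluntary", "involuntary", "planned") %in% names(cfg$admission_type_probs))) {
    stop("configuration error in `admission_type_probs`: needs voluntary, involuntary, planned",
         call. = FALSE)
  }
  if (!all(c("community", "general_ward") %in% names(cfg$route_probs))) {
    stop("configuration error in `route_probs`: needs community, general_ward",
         call. = FALSE)
  }

  p_planned <- cfg$admission_type_probs[["planned"]]
  if (is.null(cause_hazards)) {
    cause_hazards <- default_cause_hazards(names(cfg$fee_type_mix), profiles, p_planned)
  }
  if (!all(names(cfg$fee_type_mix) %in% names(cause_hazards))) {
    stop("configuration error in `cause_hazards`: needs one hazard matrix per fee type",
         call. = FALSE)
  }
  for (ft in names(cause_hazards)) {
    hz <- cause_hazards[[ft]]
    if (!is.matrix(hz) || any(hz < 0) ||
        !all(causes_terminal() %in% rownames(hz))) {
      stop(sprintf("configuration error in `cause_hazards[%s]`: must be a non-negative matrix with rows %s",
                   ft, paste(causes_terminal(), collapse = ", ")), call. = FALSE)
    }
  }
  cfg$cause_hazards <- cause_hazards

  structure(cfg, class = "generator_config")
}

# Per-fee-category hazards calibrated to the published community-discharge
# profiles, with competing events scaled to the category's non-discharged
# mass. The planned-admission point mass is removed from the targets so the
# generated cohort-level incidences hit the published values.
default_cause_hazards <- function(fee_types, profiles, p_planned) {
  out <- lapply(fee_types, function(ft) {
    row <- profiles[profiles$fee_type == ft, ]
    if (nrow(row) != 1L) {
      stop(sprintf("configuration error in `fee_type_mix`: unknown fee type `%s` (supply `cause_hazards` for custom categories)",
                   ft), call. = FALSE)
    }
    comm <- c(row$cif_community_90, row$cif_community_180,
              row$cif_community_270, row$cif_community_360)
    competing <- competing_targets_for(row$cif_community_360)
    calibrate_hazards(
      list(community = comm,
           general_ward = competing$general_ward,
           death = competing$death),
      p_planned = p_planned
    )
  })
  stats::setNames(out, fee_types)
}

#' Generator configuration calibrated to the pooled-cohort profile
#'
#' Convenience constructor for simulating a cohort whose *pooled* latent
#' event-time distribution equals the pooled-cohort targets of
#' [overall_cif_targets()]: a single overall hazard profile (adjusted for
#' the planned short-stay point mass) is applied to every fee category,
#' while the fee-category mix and all other parameters keep their defaults
#' unless overridden. Use this when the quantity of interest is the pooled
#' cumulative incidence; the default [generator_config()] instead
#' calibrates each fee category to its own published profile.
#'
#' @param n_patients Number of latent episodes.
#' @param seed Integer seed.
#' @param targets Cohort-level targets as in [overall_cif_targets()].
#' @param ... Further arguments passed to [generator_config()].
#' @return A `generator_config`.
#' @export
overall_calibrated_config <- function(n_patients,
                                      seed = 1L,
                                      targets = overall_cif_targets(),
                                      ...) {
  base <- generator_config(n_patients = n_patients, seed = seed, ...)
  hz <- calibrate_hazards(targets,
                          p_planned = base$admission_type_probs[["planned"]])
  generator_config(
    n_patients = n_patients, seed = seed,
    cause_hazards = stats::setNames(
      rep(list(hz), length(base$fee_type_mix)), names(base$fee_type_mix)),
    ...
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  %d patients, %d hospitals, %d prefectures\n",
              x$n_patients, x$n_hospitals, x$n_prefectures))
  cat(sprintf("  admission window %s .. %s, observed through %s\n",
              x$window_start, x$window_end, x$observation_end))
  cat(sprintf("  fee categories: %d; transfer prob %.3f; planned share %.3f\n",
              length(x$fee_type_mix), x$transfer_prob,
              x$admission_type_probs[["planned"]]))
  cat(sprintf("  seasonal amplitude %.2f peaking in month %d; seed %d\n",
              x$seasonal_amplitude, x$peak_month, x$seed))
  invisible(x)
}

#' Write or read a generator configuration as YAML
#'
#' Hazard matrices are stored with their interval breaks so the round trip
#' is lossless.
#'
#' @param config A [generator_config()] object.
#' @param path File path.
#' @return `read_generator_config()` returns a `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  x <- unclass(config)
  x$window_start <- as.character(x$window_start)
  x$window_end <- as.character(x$window_end)
  x$observation_end <- as.character(x$observation_end)
  for (f in c("fee_type_mix", "admission_type_probs", "route_probs",
              "sex_probs", "age_probs", "diagnosis_probs")) {
    x[[f]] <- as.list(x[[f]])   # yaml drops names of atomic vectors
  }
  x$cause_hazards <- lapply(x$cause_hazards, function(hz) {
    list(breaks = as.numeric(attr(hz, "breaks")),
         causes = rownames(hz),
         hazards = lapply(seq_len(nrow(hz)), function(i) as.numeric(hz[i, ])))
  })
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  hazards <- lapply(x$cause_hazards, function(h) {
    hz <- do.call(rbind, h$hazards)
    dimnames(hz) <- list(h$causes, paste0("d", h$breaks))
    structure(hz, breaks = h$breaks)
  })
  generator_config(
    n_patients = x$n_patients, n_hospitals = x$n_hospitals,
    n_prefectures = x$n_prefectures,
    window_start = x$window_start, window_end = x$window_end,
    observation_end = x$observation_end,
    fee_type_mix = unlist(x$fee_type_mix),
    cause_hazards = hazards,
    transfer_prob = x$transfer_prob,
    admission_type_probs = unlist(x$admission_type_probs),
    route_probs = unlist(x$route_probs),
    sex_probs = unlist(x$sex_probs),
    age_probs = unlist(x$age_probs),
    diagnosis_probs = unlist(x$diagnosis_probs),
    seasonal_amplitude = x$seasonal_amplitude,
    peak_month = x$peak_month,
    public_fund_frac = x$public_fund_frac,
    prevalent_frac = x$prevalent_frac,
    ect_background_rate = x$ect_background_rate,
    seed = x$seed
  )
}
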