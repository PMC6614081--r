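#' Reference discharge profiles for Japanese psychiatric-ward fee categories
#'
#' Japanese psychiatric units are reimbursed under three broad hospital-fee
#' plans: fee-for-service (stratified by patient-to-nurse ratio),
#' fee-for-service in advanced treatment hospitals, and per-diem payment
#' plans (some of which carry certified discharge-rate requirements, e.g.
#' psychiatric acute care units must discharge at least 40% of patients to
#' the community within 3 months). The fee category of the admitting ward is
#' the main stratifier of length-of-stay in national claims statistics.
#'
#' `fee_type_profiles()` returns one row per fee category with its national
#' share of new admissions and the cumulative incidence of community
#' discharge at 90/180/270/360 days after admission, as published for the
#' Japanese national claims cohort of fiscal years 2014-2015. These profiles
#' are the default calibration targets of the synthetic claims generator:
#' per-category piecewise-constant hazards are solved so that the latent
#' event-time distribution reproduces them exactly (see
#' [calibrate_hazards()]).
#'
#' Competing-event incidences (death, transfer to a general ward) are
#' published only for the pooled cohort (3.1% and 0.3% at 360 days); the
#' per-category defaults scale these pooled values by each category's
#' remaining non-discharged mass, so high-turnover units get proportionally
#' less competing-event incidence and dementia care units more, while the
#' admission-weighted mixture reproduces the pooled values.
#'
#' @return A tibble with columns `fee_type` (short code), `label`, `plan`,
#'   `share` (proportion of admissions), and `cif_community_90/180/270/360`
#'   (percent).
#' @export
fee_type_profiles <- function() {
  tibble::tribble(
    ~fee_type,            ~label,                                            ~plan,       ~n,      ~cif_community_90, ~cif_community_180, ~cif_community_270, ~cif_community_360,
    "ffs_10to1",          "Psychiatric unit (10:1)",                         "ffs",       11119L,  86.2, 92.2, 93.7, 94.3,
    "ffs_13to1",          "Psychiatric unit (13:1)",                         "ffs",       30721L,  74.3, 88.2, 91.4, 92.7,
    "ffs_15to1",          "Psychiatric unit (15:1)",                         "ffs",       237973L, 57.2, 73.5, 78.7, 81.4,
    "ffs_18to1",          "Psychiatric unit (18:1)",                         "ffs",       9416L,   53.8, 67.8, 73.5, 76.2,
    "ffs_20to1",          "Psychiatric unit (20:1)",                         "ffs",       2485L,   52.0, 72.7, 79.1, 81.8,
    "ffs_specialized",    "Specialized psychiatric unit",                    "ffs",       2183L,   47.9, 65.6, 71.1, 74.4,
    "adv_7to1",           "Advanced-hospital psychiatric unit (7:1)",        "advanced",  4355L,   93.8, 97.5, 98.4, 98.7,
    "adv_10to1",          "Advanced-hospital psychiatric unit (10:1)",       "advanced",  7576L,   90.6, 96.5, 97.8, 98.1,
    "adv_13to1",          "Advanced-hospital psychiatric unit (13:1)",       "advanced",  12668L,  79.8, 93.7, 96.2, 97.1,
    "adv_15to1",          "Advanced-hospital psychiatric unit (15:1)",       "advanced",  3839L,   75.9, 91.6, 95.2, 96.9,
    "pd_emergency",       "Psychiatric emergency unit",                      "per_diem",  69697L,  79.2, 92.5, 94.9, 96.0,
    "pd_acute",           "Psychiatric acute care unit",                     "per_diem",  115089L, 75.1, 91.0, 93.7, 94.8,
    "pd_emergency_phys",  "Psychiatric emergency and physical complication", "per_diem",  3034L,   80.2, 92.1, 94.8, 95.7,
    "pd_child",           "Child and adolescent psychiatric unit",           "per_diem",  4388L,   59.9, 84.6, 92.6, 95.9,
    "pd_chronic",         "Chronic psychiatric care unit",                   "per_diem",  47763L,  52.2, 65.6, 70.9, 74.1,
    "pd_dementia",        "Dementia care unit",                              "per_diem",  43676L,  38.3, 55.7, 63.4, 68.0
  ) |>
    dplyr::mutate(share = .data$n / sum(.data$n), .after = "plan") |>
    dplyr::select(-"n")
}

#' Pooled-cohort cumulative incidence calibration targets
#'
#' Target cumulative incidences (percent) at 90/180/270/360 days for the
#' pooled cohort of new psychiatric admissions: community discharge
#' 64.1%/85.7% at 90/360 days (the published headline values), with
#' 180/270-day values taken as the admission-weighted means of the
#' per-category profiles (which reproduce the headline values at the
#' endpoints); general-ward transfer and death are published at 360 days
#' only (0.3% and 3.1%), with intermediate targets ramping linearly in
#' time.
#'
#' @return A named list of numeric vectors (`community`, `general_ward`,
#'   `death`) suitable for [calibrate_hazards()].
#' @export
overall_cif_targets <- function() {
  list(
    community    = c(`90` = 64.1,  `180` = 79.2, `270` = 83.5,  `360` = 85.7),
    general_ward = c(`90` = 0.075, `180` = 0.15, `270` = 0.225, `360` = 0.3),
    death        = c(`90` = 0.775, `180` = 1.55, `270` = 2.325, `360` = 3.1)
  )
}

# Competing-event targets for one fee category: pooled 360-day values scaled
# by the category's non-discharged mass relative to the pooled cohort.
competing_targets_for <- function(cif_community_360) {
  scale <- (100 - cif_community_360) / (100 - 85.7)
  list(
    general_ward = c(`90` = 0.075, `180` = 0.15, `270` = 0.225, `360` = 0.3) * scale,
    death        = c(`90` = 0.775, `180` = 1.55, `270` = 2.325, `360` = 3.1) * scale
  )
}

default_demographics <- function() {
  list(
    sex_probs = c(men = 0.441, women = 0.559),
    age_probs = c(`0-19` = 0.029, `20-39` = 0.185, `40-64` = 0.343,
                  `65-74` = 0.165, `>=75` = 0.278),
    diagnosis_probs = c(F0 = 0.202, F1 = 0.061, F2 = 0.339, F3 = 0.225,
                        other = 0.173)
  )
}
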