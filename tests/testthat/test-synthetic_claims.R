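test_that("hazard calibration round-trips the target incidences exactly", {
  targets <- overall_cif_targets()
  hz <- calibrate_hazards(targets)
  got <- piecewise_cif(hz, c(90, 180, 270, 360))
  for (k in c("community", "general_ward", "death")) {
    expect_equal(100 * got[[k]], unname(targets[[k]]), tolerance = 1e-10)
  }
  # planned-adjusted calibration reproduces the cohort-level mixture
  hz_adj <- calibrate_hazards(targets, p_planned = 0.005)
  sub <- piecewise_cif(hz_adj, c(90, 360))
  expect_equal(100 * (0.995 * sub$community + 0.005),
               unname(targets$community[c(1, 4)]), tolerance = 1e-10)
  expect_equal(100 * 0.995 * sub$death,
               unname(targets$death[c(1, 4)]), tolerance = 1e-10)
})

test_that("calibration rejects malformed targets", {
  bad <- overall_cif_targets()
  bad$community <- rev(bad$community)
  expect_error(calibrate_hazards(bad), "nondecreasing")
  sat <- list(community = c(60, 99.8, 99.9, 99.95),
              general_ward = c(0.05, 0.1, 0.1, 0.1),
              death = c(0.05, 0.1, 0.1, 0.1))
  expect_error(calibrate_hazards(sat), "not identifiable")
  expect_error(generator_config(n_patients = -1), "n_patients")
  expect_error(generator_config(transfer_prob = 1.5), "transfer_prob")
  expect_error(generator_config(peak_month = 13), "peak_month")
  expect_error(generator_config(route_probs = c(community = 0.9, general_ward = 0.2)),
               "route_probs")
})

test_that("generation is deterministic and streams are independent", {
  cfg <- generator_config(n_patients = 500, seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  b1 <- emit_claims(generate_cohort(cfg), cfg)
  b2 <- emit_claims(generate_cohort(cfg), cfg)
  expect_identical(b1$stays, b2$stays)
  expect_identical(b1$enrollment, b2$enrollment)

  # toggling the transfer stream leaves event times and dates unchanged
  cfg0 <- generator_config(n_patients = 500, seed = 11, transfer_prob = 0)
  co <- generate_cohort(cfg)
  co0 <- generate_cohort(cfg0)
  expect_identical(co$admission_date, co0$admission_date)
  expect_identical(co$event_day, co0$event_day)
  expect_identical(co$cause, co0$cause)
})

test_that("latent marginals recover the configured mixes", {
  co <- shared_cohort()
  cfg <- shared_config()
  n <- nrow(co)
  checks <- list(
    list(p = cfg$transfer_prob, obs = mean(co$transfer)),
    list(p = cfg$route_probs[["general_ward"]], obs = mean(co$route == "general_ward")),
    list(p = cfg$admission_type_probs[["voluntary"]],
         obs = mean(co$admission_type == "voluntary")),
    list(p = cfg$sex_probs[["men"]], obs = mean(co$sex == "men")),
    list(p = cfg$diagnosis_probs[["F2"]], obs = mean(co$diagnosis == "F2")),
    list(p = cfg$age_probs[["40-64"]], obs = mean(co$age_group == "40-64")),
    list(p = cfg$fee_type_mix[["ffs_15to1"]], obs = mean(co$fee_type == "ffs_15to1"))
  )
  for (ck in checks) {
    expect_lt(abs(ck$obs - ck$p), binom99(ck$p, n) * 1.3)
  }
})

test_that("latent event times follow the closed-form cumulative incidence", {
  co <- shared_cohort()
  cfg <- shared_config()
  # within one fee category (single hazard set), per-cause conditional KS
  ft <- "ffs_15to1"
  hz <- cfg$cause_hazards[[ft]]
  sub <- co[co$fee_type == ft & co$admission_type != "planned", ]
  # P(ceiling(T) <= d) equals the continuous CIF at integer d, so binned
  # day counts can be compared to closed-form bin probabilities exactly
  edges <- c(0, 30, 60, 90, 135, 180, 270, 360, 540, 1e7)
  cf <- piecewise_cif(hz, edges)
  for (k in c("community", "death")) {
    times <- sub$event_day[!is.na(sub$cause) & sub$cause == k]
    p_bins <- diff(cf[[k]]) / max(cf[[k]])
    obs <- table(cut(times, edges))
    gof <- suppressWarnings(stats::chisq.test(as.integer(obs), p = p_bins))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("seasonality controls the admission-month distribution", {
  flat <- generator_config(n_patients = 20000, seed = 5, seasonal_amplitude = 0)
  co_flat <- generate_cohort(flat)
  tab <- table(format(co_flat$admission_date, "%Y-%m"))
  expect_length(tab, 24)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)

  peaked <- generator_config(n_patients = 20000, seed = 5,
                             seasonal_amplitude = 0.3, peak_month = 7)
  co_peak <- generate_cohort(peaked)
  by_month <- table(as.integer(format(co_peak$admission_date, "%m")))
  # summer peak, winter trough; the harmonic fit pools months and pins
  # the peak exactly
  expect_gt(by_month[["7"]], by_month[["1"]])
  fit <- fit_seasonal_poisson(monthly_counts(co_peak))
  expect_equal(fit$peak_month, 7L)
})

test_that("fragmentation yields contiguous segments and claims-style truncation", {
  co <- shared_cohort()
  cfg <- shared_config()
  b <- shared_bundle()
  stays <- b$stays[!startsWith(b$stays$patient_id, "Q"), ]

  # every transfer episode: two rows, receiving admit = sending discharge,
  # other_hospital on the first segment only
  two <- stays |> dplyr::count(patient_id) |> dplyr::filter(n == 2)
  expect_gt(nrow(two), 0)
  pair <- stays[stays$patient_id %in% two$patient_id, ] |>
    dplyr::arrange(patient_id, admit_date, is.na(discharge_date), discharge_date) |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(
      contiguous = discharge_date[1] == admit_date[2],
      first_dest = destination[1],
      hospitals_differ = hospital_id[1] != hospital_id[2]
    )
  expect_true(all(pair$contiguous))
  expect_true(all(pair$first_dest == "other_hospital"))
  expect_true(all(pair$hospitals_differ))

  # episodes without an event before observation end stay open
  open_latent <- co$patient_id[
    !is.finite(co$event_day) |
      co$admission_date + co$event_day > cfg$observation_end]
  last_row <- stays |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(open = is.na(dplyr::last(discharge_date)))
  expect_setequal(last_row$patient_id[last_row$open], open_latent)

  # enrollment markers start at least one month before first admission
  first_marker <- b$enrollment |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(first = min(month))
  first_admit <- stays |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(adm = min(admit_date))
  j <- dplyr::inner_join(first_marker, first_admit, by = "patient_id")
  expect_true(all(j$first < as.Date(format(j$adm, "%Y-%m-01"))))

  # general-ward stays end on the admission date of the episode
  gw <- dplyr::inner_join(b$general_ward, first_admit, by = "patient_id")
  expect_true(all(gw$discharge_date == gw$adm))
})

test_that("public-fund withholding removes the configured share of episodes", {
  cfg <- generator_config(n_patients = 20000, seed = 9, public_fund_frac = 0.19)
  co <- generate_cohort(cfg)
  b <- emit_claims(co, cfg)
  ratio <- length(unique(b$stays$patient_id)) / nrow(co)
  expect_lt(abs(ratio - 0.81), binom99(0.81, nrow(co)) * 1.3)
  expect_length(attr(b, "withheld"), nrow(co) - length(unique(b$stays$patient_id)))
})

test_that("id-error injection merges the requested share of patients", {
  b <- shared_bundle()
  expect_identical(inject_id_errors(b$stays, 0), b$stays)
  expect_error(inject_id_errors(b$stays, 1.2), "collision_rate")

  merged <- inject_id_errors(b$stays, 0.01, seed = 3)
  n_ids <- length(unique(b$stays$patient_id))
  n_shared <- 2 * nrow(attr(merged, "merged_ids"))
  expect_lt(abs(n_shared / n_ids - 0.01), 0.003)
})

test_that("claims bundles and configs round-trip through disk", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(n_patients = 200, seed = 2, prevalent_frac = 0.05)
  co <- generate_cohort(cfg)
  b <- emit_claims(co, cfg)
  write_claims(b, dir, latent = co)
  back <- read_claims(dir)
  expect_equal(as.data.frame(back$stays), as.data.frame(b$stays))
  expect_equal(as.data.frame(back$enrollment), as.data.frame(b$enrollment))
  expect_equal(as.data.frame(back$general_ward), as.data.frame(b$general_ward))

  cfg_path <- file.path(dir, "config.yaml")
  write_generator_config(cfg, cfg_path)
  cfg2 <- read_generator_config(cfg_path)
  expect_equal(cfg2$fee_type_mix, cfg$fee_type_mix)
  expect_equal(cfg2$cause_hazards[["pd_acute"]], cfg$cause_hazards[["pd_acute"]],
               tolerance = 1e-12)
  expect_identical(generate_cohort(cfg2), co)
})
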