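test_that("linkage chains transfers and keeps first-segment attribution", {
  linked <- link_segments(tiny_stays())
  expect_equal(nrow(linked), 3)

  a <- linked[linked$patient_id == "A", ]
  expect_false(a$transfer)
  expect_equal(a$n_segments, 1L)

  b <- linked[linked$patient_id == "B", ]
  expect_true(b$transfer)
  expect_equal(b$n_segments, 2L)
  expect_equal(b$fee_type, "ffs_15to1")       # admitting segment
  expect_equal(b$hospital_id, "H1")
  expect_equal(b$final_destination, "community")
  expect_equal(b$admission_date, as.Date("2014-06-01"))
  expect_equal(b$last_discharge_date, as.Date("2014-09-15"))

  cc <- linked[linked$patient_id == "C", ]
  expect_true(is.na(cc$last_discharge_date))  # still hospitalized

  seg <- episode_segments(linked)
  expect_equal(nrow(seg), 4)
  expect_equal(dplyr::n_distinct(seg$episode_id), 3)
})

test_that("linkage respects the gap tolerance and validates stays", {
  stays <- tiny_stays()
  # push B's second admission two days past the discharge: no longer chained
  stays$admit_date[3] <- stays$discharge_date[2] + 2
  stays$destination[2] <- "community"
  linked <- link_segments(stays, gap_days = 1)
  expect_equal(nrow(linked), 4)
  linked2 <- link_segments(stays, gap_days = 2)
  expect_equal(nrow(linked2), 3)

  bad <- tiny_stays()
  bad$discharge_date[1] <- bad$admit_date[1] - 5
  expect_error(link_segments(bad), "discharge before admission")
  bad2 <- tiny_stays()
  bad2$destination[4] <- "community"
  expect_error(link_segments(bad2), "destination")
})

test_that("fragmentation then linkage recovers the latent episodes exactly", {
  co <- shared_cohort()
  cfg <- shared_config()
  b <- shared_bundle()
  linked <- link_segments(b$stays, gap_days = 1)
  linked <- linked[!startsWith(linked$patient_id, "Q"), ]  # drop prevalent extras

  expect_equal(nrow(linked), nrow(co))
  m <- dplyr::inner_join(
    co, linked, by = "patient_id", suffix = c("_true", "_linked"))
  expect_equal(nrow(m), nrow(co))
  expect_identical(m$admission_date_true, m$admission_date_linked)
  expect_identical(m$fee_type_true, m$fee_type_linked)
  expect_identical(m$hospital_id_true, m$hospital_id_linked)

  # observable end date: latent event date if it falls inside observation
  exp_end <- m$admission_date_true +
    ifelse(is.finite(m$event_day), m$event_day, NA)
  exp_end[!is.na(exp_end) & exp_end > cfg$observation_end] <- NA
  expect_identical(as.numeric(m$last_discharge_date), as.numeric(exp_end))

  # observable transfer flag: transfer whose date falls inside observation
  exp_transfer <- m$transfer_true &
    (m$admission_date_true + m$transfer_day) <= cfg$observation_end
  expect_identical(m$transfer_linked, exp_transfer)

  # outcome assignment against the latent truth under dual censoring
  ep <- assign_outcome(linked, cfg$observation_end, 365L)
  m2 <- dplyr::inner_join(co, ep, by = "patient_id", suffix = c("_true", ""))
  boundary <- pmin(cfg$observation_end, m2$admission_date_true + 365)
  event_obs <- is.finite(m2$event_day) &
    (m2$admission_date_true + m2$event_day) <= boundary
  expect_identical(m2$outcome, ifelse(event_obs, m2$cause, "censored"))
  expect_identical(
    m2$event_time,
    pmax(1L, as.integer(ifelse(event_obs, m2$event_day,
                               boundary - m2$admission_date_true))))
})

test_that("cohort filters remove prevalent, unverified, and same-day cases with full accounting", {
  win <- as.Date("2014-04-01")
  stays <- dplyr::bind_rows(
    tiny_stays(),
    tibble::tibble(   # prevalent: admitted before window, still in ward at start
      patient_id = "D", hospital_id = "H1", prefecture = 1L,
      fee_code = "pd_chronic",
      admit_date = as.Date("2014-03-15"), discharge_date = as.Date("2014-05-01"),
      destination = "community", legal_type = "voluntary", ect = FALSE,
      diagnosis = "F2", sex = "men", age_group = "40-64"),
    tibble::tibble(   # id-error collision: overlapping stays in two hospitals
      patient_id = "E", hospital_id = c("H1", "H2"), prefecture = 1L,
      fee_code = "ffs_15to1",
      admit_date = as.Date(c("2014-05-01", "2014-05-10")),
      discharge_date = as.Date(c("2014-06-01", "2014-05-20")),
      destination = "community", legal_type = "voluntary", ect = FALSE,
      diagnosis = "F2", sex = "men", age_group = "40-64")
  )
  enrollment <- dplyr::bind_rows(
    tiny_enrollment(),
    tibble::tibble(patient_id = c("D", "E"), month = as.Date("2014-01-01"))
  )
  # A has no marker before admission month and no earlier claim: unverified
  enrollment <- enrollment[!(enrollment$patient_id == "A" &
                               enrollment$month < as.Date("2014-05-01")), ]

  linked <- link_segments(stays)
  res <- apply_cohort_filters(linked, enrollment, window_start = win)
  log <- res$log
  get <- function(rule) log$removed[log$rule == rule]

  # E's overlapping stays chain into one episode, removed whole
  expect_equal(get("same_day_multi_hospital"), 1)
  expect_false("E" %in% res$episodes$patient_id)
  expect_equal(get("prevalent_at_window_start"), 1)
  expect_equal(get("enrollment_unverified"), 1)
  expect_equal(get("retained"), nrow(res$episodes))
  expect_equal(sum(log$removed), nrow(linked))     # retained + removed = input
  expect_setequal(res$episodes$patient_id, c("B", "C"))

  # a transfer's boundary-day contact is not a same-day multi-hospital error
  expect_true("B" %in% res$episodes$patient_id)

  # empty input yields an empty output and a zeroed log
  empty <- apply_cohort_filters(linked[0, ], enrollment, window_start = win)
  expect_equal(nrow(empty$episodes), 0)
  expect_true(all(empty$log$removed == 0))
})

test_that("enrollment can be verified by an earlier claim alone", {
  stays <- tiny_stays()[1, ]
  readmit <- stays
  readmit$admit_date <- as.Date("2014-08-01")
  readmit$discharge_date <- as.Date("2014-08-20")
  both <- dplyr::bind_rows(stays, readmit)
  linked <- link_segments(both)
  # no markers at all: first admission unverified, second verified by the first claim
  res <- apply_cohort_filters(linked, tiny_enrollment()[0, ])
  expect_equal(nrow(res$episodes), 1)
  expect_equal(res$episodes$admission_date, as.Date("2014-08-01"))
})

test_that("outcome assignment applies the dual censoring rule", {
  mk <- function(adm, dis, dest) {
    s <- tiny_stays()[1, ]
    s$admit_date <- as.Date(adm)
    s$discharge_date <- as.Date(dis)
    s$destination <- dest
    assign_outcome(link_segments(s))
  }
  # still hospitalized at observation end
  late <- mk("2016-03-01", NA, NA)
  expect_equal(late$outcome, "censored")
  expect_equal(late$event_time, 213L)
  # discharge beyond 365 days: censored at 365
  long <- mk("2014-06-01", "2015-07-06", "community")
  expect_equal(long$outcome, "censored")
  expect_equal(long$event_time, 365L)
  # event inside both boundaries
  ok <- mk("2014-06-01", "2014-07-16", "community")
  expect_equal(ok$outcome, "community")
  expect_equal(ok$event_time, 45L)
  # same-day discharge floored to one day
  sameday <- mk("2014-06-01", "2014-06-01", "death")
  expect_equal(sameday$event_time, 1L)

  dangling <- tiny_stays()[2, ]  # other_hospital with no receiving stay
  expect_error(assign_outcome(link_segments(dangling)), "unterminated")
})

test_that("admission type and route classification follow their rules", {
  s <- tiny_stays()[1, ]
  s$ect <- TRUE
  s$discharge_date <- s$admit_date + 3
  ep <- classify_admission(assign_outcome(link_segments(s)))
  expect_equal(ep$admission_type, "planned")       # ECT and LOS <= 3

  s$discharge_date <- s$admit_date + 10
  ep <- classify_admission(assign_outcome(link_segments(s)))
  expect_equal(ep$admission_type, "voluntary")     # ECT but LOS > 3

  s2 <- tiny_stays()[1, ]
  s2$legal_type <- "involuntary"
  s2$discharge_date <- s2$admit_date + 2
  ep <- classify_admission(assign_outcome(link_segments(s2)))
  expect_equal(ep$admission_type, "involuntary")   # short stay without ECT

  gw <- tibble::tibble(patient_id = "A", hospital_id = "H9",
                       admit_date = as.Date("2014-04-20"),
                       discharge_date = as.Date("2014-05-01"))
  ep <- classify_route(assign_outcome(link_segments(tiny_stays())), gw)
  expect_equal(ep$route[ep$patient_id == "A"], "general_ward")
  expect_equal(ep$route[ep$patient_id == "B"], "community")
  # a day-before discharge also counts
  gw$discharge_date <- as.Date("2014-04-30")
  ep <- classify_route(assign_outcome(link_segments(tiny_stays())), gw)
  expect_equal(ep$route[ep$patient_id == "A"], "general_ward")
})

test_that("full pipeline recovers classification shares and transfer prevalence", {
  co <- shared_cohort()
  cfg <- shared_config()
  built <- shared_built()
  ep <- built$episodes
  n <- nrow(ep)
  expect_equal(n, nrow(co))   # clean claims: nothing removed

  p_transfer <- cfg$transfer_prob
  expect_lt(abs(mean(ep$transfer) - p_transfer), binom99(p_transfer, n) * 1.3)
  for (ty in names(cfg$admission_type_probs)) {
    p <- cfg$admission_type_probs[[ty]]
    expect_lt(abs(mean(ep$admission_type == ty) - p), binom99(p, n) * 1.3)
  }
  p_gw <- cfg$route_probs[["general_ward"]]
  expect_lt(abs(mean(ep$route == "general_ward") - p_gw), binom99(p_gw, n) * 1.3)

  # prevalent extras were injected and excluded
  expect_equal(built$filter_log$removed[
    built$filter_log$rule == "prevalent_at_window_start"],
    round(cfg$prevalent_frac * cfg$n_patients))

  # every emitted stay is accounted for: in a retained episode or excluded
  seg <- episode_segments(ep)
  expect_equal(dplyr::n_distinct(seg$episode_id), n)
})

test_that("id collisions surface as same-day multi-hospital exclusions", {
  cfg <- generator_config(n_patients = 2000, seed = 13)
  b <- emit_claims(generate_cohort(cfg), cfg)
  stays <- inject_id_errors(b$stays, 0.02, seed = 4)
  linked <- link_segments(stays)
  res <- apply_cohort_filters(linked, b$enrollment)
  removed <- res$log$removed[res$log$rule == "same_day_multi_hospital"]
  expect_gt(removed, 0)
  # merged pseudo-patients with truly overlapping stays are all gone
  merged <- attr(stays, "merged_ids")
  overlapping <- intersect(merged$survivor, res$episodes$patient_id)
  seg <- episode_segments(res$episodes)
  for (pid in overlapping) {
    s <- seg[seg$patient_id == pid, ]
    s_end <- dplyr::coalesce(s$discharge_date, as.Date("9999-12-31"))
    clash <- FALSE
    if (nrow(s) > 1) {
      for (i in seq_len(nrow(s) - 1)) {
        for (j in seq(i + 1, nrow(s))) {
          if (s$hospital_id[i] != s$hospital_id[j] &&
              max(s$admit_date[i], s$admit_date[j]) <
                min(s_end[i], s_end[j])) clash <- TRUE
        }
      }
    }
    expect_false(clash)
  }
})

test_that("filters are monotone: adding a stay never resurrects a removed episode", {
  stays <- tiny_stays()
  enr <- tiny_enrollment()
  enr <- enr[!(enr$patient_id == "A" & enr$month < as.Date("2014-05-01")), ]
  res1 <- apply_cohort_filters(link_segments(stays), enr)
  removed1 <- setdiff(stays$patient_id, res1$episodes$patient_id)
  extra <- tiny_stays()[4, ]
  extra$patient_id <- "Z"
  res2 <- apply_cohort_filters(link_segments(dplyr::bind_rows(stays, extra)), enr)
  expect_true(all(removed1 %in% setdiff(c(stays$patient_id, "Z"),
                                        res2$episodes$patient_id)))
})
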