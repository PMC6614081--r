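# Shared synthetic fixtures, generated once per test run and memoized.

memo <- local({
  cache <- new.env(parent = emptyenv())
  function(key, value) {
    if (!exists(key, envir = cache)) assign(key, force(value), envir = cache)
    get(key, envir = cache)
  }
})

# Mid-sized cohort under default (per-fee-category) calibration.
shared_config <- function() {
  generator_config(n_patients = 20000, seed = 42, prevalent_frac = 0.01)
}
shared_cohort <- function() memo("cohort", generate_cohort(shared_config()))
shared_bundle <- function() memo("bundle", emit_claims(shared_cohort(), shared_config()))
shared_built <- function() memo("built", build_episodes(shared_bundle()))

# Small hand-made stay table: one plain stay, one transfer pair, one open stay.
tiny_stays <- function() {
  tibble::tibble(
    patient_id = c("A", "B", "B", "C"),
    hospital_id = c("H1", "H1", "H2", "H3"),
    prefecture = c(1L, 1L, 2L, 3L),
    fee_code = c("pd_acute", "ffs_15to1", "pd_chronic", "ffs_15to1"),
    admit_date = as.Date(c("2014-05-01", "2014-06-01", "2014-07-01", "2014-08-01")),
    discharge_date = as.Date(c("2014-05-20", "2014-07-01", "2014-09-15", NA)),
    destination = c("community", "other_hospital", "community", NA),
    legal_type = c("voluntary", "involuntary", "involuntary", "voluntary"),
    ect = c(FALSE, FALSE, FALSE, FALSE),
    diagnosis = c("F2", "F3", "F3", "F0"),
    sex = c("men", "women", "women", "men"),
    age_group = c("40-64", "20-39", "20-39", ">=75")
  )
}

tiny_enrollment <- function() {
  tidyr::crossing(
    patient_id = c("A", "B", "C"),
    month = seq(as.Date("2014-01-01"), as.Date("2016-09-01"), by = "month")
  )
}

# Binomial 99% half-width (in proportion units) for a share p at size n.
binom99 <- function(p, n) stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
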