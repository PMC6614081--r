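#' Solve piecewise-constant cause-specific hazards from target cumulative incidences
#'
#' Given target cumulative incidence values for each cause (community
#' discharge, general-ward transfer, in-ward death) at a grid of horizons,
#' solves for the piecewise-constant daily cause-specific hazards on the
#' intervals between horizons that reproduce those targets exactly under the
#' competing-risks identity
#' \deqn{CIF_k(t) = \int_0^t \lambda_k(u) S(u)\,du, \quad
#'       S(t) = \exp\{-\sum_k \Lambda_k(t)\}.}
#' The solution is sequential and exact: on each interval the all-cause
#' hazard follows from the log-ratio of event-free survival at the interval
#' ends (survival being one minus total cumulative incidence), and the
#' cause-specific split is proportional to the cause-specific CIF increments.
#' The hazard of the final interval is extrapolated beyond the last horizon.
#'
#' When a fraction `p_planned` of the cohort consists of planned short-stay
#' admissions (electroconvulsive therapy, length of stay of at most 3 days,
#' discharged to the community), the targets are interpreted as
#' cohort-level values and deflated so that the mixture of the hazard-driven
#' majority and the planned point mass reproduces them: for horizons beyond
#' 3 days, community targets become `(c - p)/(1 - p)` and competing-event
#' targets `c/(1 - p)`.
#'
#' @param targets Named list with numeric vectors `community`,
#'   `general_ward`, `death`, each giving the cumulative incidence in
#'   percent at `horizons`. Each vector must be nondecreasing and the three
#'   must total less than 100 at every horizon.
#' @param horizons Integer days, strictly increasing; default
#'   `c(90, 180, 270, 360)`.
#' @param p_planned Fraction of planned short-stay admissions the cohort
#'   targets include (default 0).
#' @return A matrix of daily hazards with one row per cause and one column
#'   per interval `[0,h1), [h1,h2), ...` (the last extending to infinity),
#'   with the horizons stored in attribute `"breaks"`.
#' @seealso [piecewise_cif()] for the closed-form inverse.
#' @export
#' @examples
#' hz <- calibrate_hazards(list(
#'   community    = c(64.1, 79.2, 83.5, 85.7),
#'   general_ward = c(0.075, 0.15, 0.225, 0.3),
#'   death        = c(0.775, 1.55, 2.325, 3.1)
#' ))
#' piecewise_cif(hz, c(90, 360))$community  # recovers 0.641, 0.857
calibrate_hazards <- function(targets,
                              horizons = c(90L, 180L, 270L, 360L),
                              p_planned = 0) {
  causes <- causes_terminal()
  if (!all(causes %in% names(targets))) {
    stop("`targets` must contain components ", paste(causes, collapse = ", "),
         call. = FALSE)
  }
  horizons <- as.numeric(horizons)
  if (is.unsorted(horizons, strictly = TRUE) || any(horizons <= 0)) {
    stop("`horizons` must be positive and strictly increasing", call. = FALSE)
  }
  assert_fraction(p_planned, "p_planned")

  tg <- do.call(rbind, lapply(causes, function(k) {
    v <- as.numeric(targets[[k]]) / 100
    if (length(v) != length(horizons)) {
      stop(sprintf("`targets$%s` must have one value per horizon", k), call. = FALSE)
    }
    v
  }))
  rownames(tg) <- causes

  # Deflate cohort-level targets to the hazard-driven subpopulation.
  if (p_planned > 0) {
    tg["community", ] <- (tg["community", ] - p_planned) / (1 - p_planned)
    tg[c("general_ward", "death"), ] <-
      tg[c("general_ward", "death"), ] / (1 - p_planned)
  }

  if (any(tg < 0)) {
    stop("targets imply a negative subpopulation incidence; ",
         "check `p_planned` against the community targets", call. = FALSE)
  }
  if (any(t(apply(tg, 1, diff)) < -1e-12)) {
    stop("each cause's targets must be nondecreasing across horizons", call. = FALSE)
  }

  surv <- c(1, 1 - colSums(tg))
  if (any(surv <= 0)) {
    stop("total cumulative incidence reaches 100% within the horizon grid; ",
         "hazards are not identifiable", call. = FALSE)
  }

  widths <- diff(c(0, horizons))
  inc <- cbind(tg[, 1], t(apply(tg, 1, diff)))  # per-interval CIF increments
  hz <- matrix(0, nrow = length(causes), ncol = length(horizons),
               dimnames = list(causes, paste0("d", c(0, horizons[-length(horizons)]))))
  for (j in seq_along(horizons)) {
    total_inc <- sum(inc[, j])
    if (total_inc <= 0) next
    lambda_all <- log(surv[j] / surv[j + 1]) / widths[j]
    hz[, j] <- lambda_all * inc[, j] / total_inc
  }
  structure(hz, breaks = c(0, horizons[-length(horizons)]))
}

#' Closed-form cumulative incidence implied by piecewise-constant hazards
#'
#' Evaluates the exact cause-specific cumulative incidence functions and the
#' event-free survival implied by piecewise-constant daily cause-specific
#' hazards. This is the analytic ground truth against which estimates from
#' simulated cohorts are compared.
#'
#' @param hazards Matrix as returned by [calibrate_hazards()]: rows are
#'   causes, columns are intervals, attribute `"breaks"` holds the interval
#'   start days (first must be 0).
#' @param times Numeric vector of days (>= 0) at which to evaluate.
#' @return A tibble with columns `time`, `survival`, and one column per
#'   cause holding its cumulative incidence (proportions in [0, 1]).
#' @export
piecewise_cif <- function(hazards, times) {
  breaks <- attr(hazards, "breaks")
  if (is.null(breaks)) breaks <- c(0, 90, 180, 270)
  stopifnot(breaks[1] == 0, ncol(hazards) == length(breaks))
  times <- as.numeric(times)
  if (any(times < 0)) stop("`times` must be non-negative", call. = FALSE)

  lambda_all <- colSums(hazards)
  widths <- diff(c(breaks, Inf))
  # survival and per-cause CIF at interval starts
  cum_haz_start <- cumsum(c(0, (lambda_all * widths)[-length(widths)]))
  s_start <- exp(-cum_haz_start)
  cif_start <- matrix(0, nrow = nrow(hazards), ncol = length(breaks))
  for (j in seq_along(breaks)[-1]) {
    jm <- j - 1L
    gain <- if (lambda_all[jm] > 0) {
      (hazards[, jm] / lambda_all[jm]) * (s_start[jm] - s_start[j])
    } else rep(0, nrow(hazards))
    cif_start[, j] <- cif_start[, jm] + gain
  }

  idx <- findInterval(times, breaks)
  dt <- times - breaks[idx]
  s_t <- s_start[idx] * exp(-lambda_all[idx] * dt)
  cif_t <- vapply(seq_along(times), function(i) {
    j <- idx[i]
    gain <- if (lambda_all[j] > 0) {
      (hazards[, j] / lambda_all[j]) * (s_start[j] - s_t[i])
    } else rep(0, nrow(hazards))
    cif_start[, j] + gain
  }, numeric(nrow(hazards)))

  out <- tibble::tibble(time = times, survival = s_t)
  for (k in seq_len(nrow(hazards))) out[[rownames(hazards)[k]]] <- cif_t[k, ]
  out
}

# Draw one latent event time and cause per subject from piecewise-constant
# cause-specific hazards by inverting the all-cause cumulative hazard.
# Returns continuous times; +Inf (cause NA) if the total hazard is exhausted.
sample_piecewise_events <- function(n, hazards) {
  breaks <- attr(hazards, "breaks")
  lambda_all <- colSums(hazards)
  widths <- diff(c(breaks, Inf))
  hz_w <- lambda_all * widths
  hz_w[lambda_all == 0] <- 0                      # 0 * Inf on an exhausted last interval
  cum_end <- cumsum(hz_w)                         # cumulative hazard at interval ends
  cum_start <- c(0, cum_end[-length(cum_end)])

  e <- stats::rexp(n)
  j <- findInterval(e, cum_start)                 # interval where target is reached
  time <- rep(Inf, n)
  ok <- lambda_all[j] > 0 & is.finite((e - cum_start[j]) / lambda_all[j])
  time[ok] <- breaks[j[ok]] + (e[ok] - cum_start[j[ok]]) / lambda_all[j[ok]]

  cause <- rep(NA_character_, n)
  u <- stats::runif(n)
  for (jj in unique(j[ok])) {
    sel <- ok & j == jj
    p <- hazards[, jj] / lambda_all[jj]
    cause[sel] <- rownames(hazards)[findInterval(u[sel], cumsum(p), left.open = TRUE) + 1L]
  }
  list(time = time, cause = cause)
}
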