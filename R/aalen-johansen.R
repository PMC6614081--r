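#' Aalen-Johansen estimator of cause-specific cumulative incidence
#'
#' Nonparametric estimation of the cumulative incidence functions of
#' competing discharge destinations (community, general ward, death) under
#' right censoring. At each distinct event time \eqn{t_j} with \eqn{n_j}
#' subjects at risk and \eqn{d_{kj}} cause-\eqn{k} events,
#' \deqn{\hat S(t_j) = \hat S(t_{j-1})\,\bigl(1 - \textstyle\sum_k d_{kj}/n_j\bigr),
#'   \qquad
#'   \widehat{CIF}_k(t_j) = \widehat{CIF}_k(t_{j-1}) + \hat S(t_{j-1})\,d_{kj}/n_j.}
#' Censored subjects leave the risk set after their censoring time (events
#' precede censorings at ties); ties among events at one time are processed
#' jointly. Curves are right-continuous step functions; by construction
#' \eqn{\sum_k \widehat{CIF}_k(t) + \hat S(t) = 1} at every step.
#'
#' A pointwise variance of each cumulative incidence (the delta-method
#' estimator of Marubini and Valsecchi, as used by standard
#' competing-risks software) is returned when `variance = TRUE`.
#'
#' @param time Positive event/censoring times in days (>= 1).
#' @param cause Character vector: one of `causes` or `"censored"`.
#' @param causes Closed set of competing causes (default community,
#'   general_ward, death).
#' @param variance Also compute pointwise variances (default TRUE).
#' @return An object of class `cif_curve`: a list with `time` (sorted
#'   distinct event times), `n_risk`, `n_event` (matrix, one column per
#'   cause), `survival`, `cif` (matrix), optionally `var_cif`, and `n` (the
#'   sample size).
#' @export
#' @examples
#' fit <- aalen_johansen(c(1, 2, 3, 4), c("community", "death", "censored",
#'                                        "community"))
#' cif_at(fit, "community", 4)  # 0.75
aalen_johansen <- function(time, cause,
                           causes = causes_terminal(),
                           variance = TRUE) {
  if (length(time) == 0) stop("empty sample", call. = FALSE)
  if (length(time) != length(cause)) {
    stop("`time` and `cause` must have equal length", call. = FALSE)
  }
  if (any(is.na(time)) || any(time < 1)) {
    stop("times must be >= 1 and non-missing", call. = FALSE)
  }
  unknown <- setdiff(unique(cause), c(causes, "censored"))
  if (length(unknown)) {
    stop("unknown cause label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n <- length(time)
  is_event <- cause != "censored"
  tj <- sort(unique(time[is_event]))

  if (length(tj) == 0) {  # all censored: flat curve at the censoring times
    tj <- sort(unique(time))
    zero <- matrix(0, length(tj), length(causes),
                   dimnames = list(NULL, causes))
    out <- list(time = tj,
                n_risk = vapply(tj, function(t) sum(time >= t), numeric(1)),
                n_event = zero, survival = rep(1, length(tj)), cif = zero,
                var_cif = if (variance) zero, n = n, causes = causes)
    return(structure(out, class = "cif_curve"))
  }

  n_risk <- vapply(tj, function(t) sum(time >= t), numeric(1))
  d <- vapply(causes, function(k) {
    vapply(tj, function(t) sum(time == t & cause == k), numeric(1))
  }, numeric(length(tj)))
  d <- matrix(d, nrow = length(tj), dimnames = list(NULL, causes))
  d_all <- rowSums(d)

  s_prev <- c(1, cumprod(1 - d_all / n_risk))[seq_along(tj)]
  surv <- cumprod(1 - d_all / n_risk)
  cif <- apply(d / n_risk * s_prev, 2, cumsum)
  cif <- matrix(cif, nrow = length(tj), dimnames = list(NULL, causes))

  var_cif <- NULL
  if (variance) {
    var_cif <- matrix(0, length(tj), length(causes),
                      dimnames = list(NULL, causes))
    # delta-method pointwise variance; guard the Greenwood factor when the
    # risk set is exhausted
    gw_den <- n_risk * pmax(n_risk - d_all, 1)
    for (k in seq_along(causes)) {
      inc <- s_prev * d[, k] / n_risk
      for (i in seq_along(tj)) {
        Fi <- cif[i, k]
        j <- seq_len(i)
        term1 <- sum((Fi - cif[j, k])^2 * d_all[j] / gw_den[j])
        term2 <- sum(s_prev[j]^2 * ((n_risk[j] - d[j, k]) / n_risk[j]) *
                       d[j, k] / n_risk[j]^2)
        term3 <- -2 * sum((Fi - cif[j, k]) * s_prev[j] * d[j, k] / n_risk[j]^2)
        var_cif[i, k] <- term1 + term2 + term3
      }
    }
  }

  structure(list(time = tj, n_risk = n_risk, n_event = d, survival = surv,
                 cif = cif, var_cif = var_cif, n = n, causes = causes),
            class = "cif_curve")
}

#' Evaluate a cumulative incidence curve at given times
#'
#' Right-continuous step-function lookup: the value at the largest event
#' time less than or equal to `t`, and 0 before the first event time.
#' Evaluation exactly at an event time includes that time's events, so
#' "within 90 days" means up to and including day 90.
#'
#' @param curve A `cif_curve` from [aalen_johansen()].
#' @param cause One of the curve's causes, or `"survival"` for the
#'   event-free survival (which starts at 1).
#' @param t Times in days (>= 0); vectorized.
#' @return Proportions in [0, 1].
#' @export
cif_at <- function(curve, cause, t) {
  stopifnot(inherits(curve, "cif_curve"))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  idx <- findInterval(t, curve$time)
  if (identical(cause, "survival")) {
    return(ifelse(idx == 0, 1, curve$survival[pmax(idx, 1)]))
  }
  if (!cause %in% curve$causes) {
    stop("unknown cause label: ", cause, call. = FALSE)
  }
  ifelse(idx == 0, 0, curve$cif[pmax(idx, 1), cause])
}

#' Standard error of a cumulative incidence at given times
#'
#' @inheritParams cif_at
#' @return Standard errors (0 before the first event time).
#' @export
cif_se_at <- function(curve, cause, t) {
  stopifnot(inherits(curve, "cif_curve"))
  if (is.null(curve$var_cif)) {
    stop("curve was computed with variance = FALSE", call. = FALSE)
  }
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 0, sqrt(pmax(curve$var_cif[pmax(idx, 1), cause], 0)))
}

#' Kaplan-Meier product-limit estimator of event-free survival
#'
#' All-cause product-limit estimator, the single-decrement component of the
#' Aalen-Johansen estimator: with one cause and no competing events,
#' `1 - km_event_free()` equals the Aalen-Johansen cumulative incidence.
#'
#' @param time Positive times in days.
#' @param event Logical (or 0/1): TRUE for an event, FALSE for censoring.
#' @return A tibble with `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_event_free <- function(time, event) {
  if (length(time) == 0) stop("empty sample", call. = FALSE)
  event <- as.logical(event)
  tj <- sort(unique(time[event]))
  if (length(tj) == 0) {
    return(tibble::tibble(time = sort(unique(time)),
                          n_risk = vapply(sort(unique(time)),
                                          function(t) sum(time >= t), numeric(1)),
                          n_event = 0, survival = 1))
  }
  n_risk <- vapply(tj, function(t) sum(time >= t), numeric(1))
  d <- vapply(tj, function(t) sum(time == t & event), numeric(1))
  tibble::tibble(time = tj, n_risk = n_risk, n_event = d,
                 survival = cumprod(1 - d / n_risk))
}

#' Export a cumulative incidence curve as a tidy table
#'
#' One row per event time and cause, suitable for plotting the cumulative
#' incidence of discharge over days since admission.
#'
#' @param curve A `cif_curve`.
#' @return A tibble with `time`, `cause`, `cif`, `survival`, `n_at_risk`.
#' @export
tidy_cif <- function(curve) {
  stopifnot(inherits(curve, "cif_curve"))
  purrr::map_dfr(curve$causes, function(k) {
    tibble::tibble(time = curve$time, cause = k, cif = curve$cif[, k],
                   survival = curve$survival, n_at_risk = curve$n_risk)
  })
}

#' @export
print.cif_curve <- function(x, ...) {
  cat(sprintf("<cif_curve> n = %d, %d event times, causes: %s\n",
              x$n, length(x$time), paste(x$causes, collapse = ", ")))
  horizons <- c(90, 180, 270, 360)
  horizons <- horizons[horizons <= max(x$time)]
  if (length(horizons)) {
    for (k in x$causes) {
      cat(sprintf("  %-14s %s\n", k,
                  paste(sprintf("%5.1f%% @%dd",
                                100 * cif_at(x, k, horizons), horizons),
                        collapse = "  ")))
    }
  }
  invisible(x)
}
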