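#' Monthly counts of new admissions
#'
#' Tallies episodes by calendar month of admission over the study window;
#' months without admissions appear with a zero count.
#'
#' @param episodes Episode table with an `admission_date` column.
#' @param window_start,window_end Inclusive window; defaults to the range
#'   of admission dates.
#' @return A tibble with `month` (first-of-month date), `month_index`
#'   (1..n), `calendar_month` (1-12), and `count`.
#' @export
monthly_counts <- function(episodes, window_start = NULL, window_end = NULL) {
  window_start <- window_start %||% suppressWarnings(min(episodes$admission_date))
  window_end <- window_end %||% suppressWarnings(max(episodes$admission_date))
  if (!is.finite(as.numeric(as.Date(window_start))) ||
      !is.finite(as.numeric(as.Date(window_end))) ||
      as.Date(window_end) < as.Date(window_start)) {
    stop("empty or invalid window", call. = FALSE)
  }
  months <- month_seq(window_start, window_end)
  counted <- episodes |>
    dplyr::mutate(month = month_floor(.data$admission_date)) |>
    dplyr::count(.data$month, name = "count")
  tibble::tibble(month = months) |>
    dplyr::left_join(counted, by = "month") |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      month_index = dplyr::row_number(),
      calendar_month = as.integer(format(.data$month, "%m"))
    ) |>
    dplyr::select("month", "month_index", "calendar_month", "count")
}

#' Seasonal Poisson model for monthly admission counts
#'
#' Fits a log-linear Poisson regression with a linear secular trend and a
#' first-harmonic seasonal component,
#' \deqn{\log \mu_m = \beta_0 + \beta_1 m + a \sin(2\pi c_m/12) + b \cos(2\pi c_m/12),}
#' where \eqn{m} is the month index and \eqn{c_m} the calendar month. This
#' is a deliberately simple, fully specified stand-in for smoother-based
#' trend models: it captures a single seasonal peak and a secular drift,
#' and its peak month and amplitude are closed-form functions of the
#' coefficients. Fitting is by iteratively reweighted least squares
#' (convergence when the relative deviance change is below 1e-10, at most
#' 100 iterations).
#'
#' @param series A tibble from [monthly_counts()] (needs `month_index`,
#'   `calendar_month`, `count`), at least 12 months.
#' @return An object of class `seasonal_fit`: coefficients (`intercept`,
#'   `trend`, `sin` = a, `cos` = b), `amplitude` \eqn{\sqrt{a^2+b^2}},
#'   `peak_month` (calendar month maximizing the fitted seasonal
#'   component), `deviance`, `fitted`, and the underlying `glm` object.
#' @export
fit_seasonal_poisson <- function(series) {
  needed <- c("month_index", "calendar_month", "count")
  if (!all(needed %in% names(series))) {
    stop("`series` must come from monthly_counts()", call. = FALSE)
  }
  if (nrow(series) < 12) stop("need at least 12 months", call. = FALSE)
  if (all(series$count == 0)) stop("all counts are zero", call. = FALSE)

  dat <- data.frame(
    count = series$count,
    t = series$month_index,
    s = sin(2 * pi * series$calendar_month / 12),
    c = cos(2 * pi * series$calendar_month / 12)
  )
  fit <- stats::glm(count ~ t + s + c, family = stats::poisson(), data = dat,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    stop(sprintf("seasonal fit did not converge in %d IRLS iterations (deviance %.6g)",
                 fit$iter, fit$deviance), call. = FALSE)
  }
  cf <- stats::coef(fit)
  a <- unname(cf["s"]); b <- unname(cf["c"])
  seasonal <- a * sin(2 * pi * (1:12) / 12) + b * cos(2 * pi * (1:12) / 12)
  structure(list(
    intercept = unname(cf["(Intercept)"]),
    trend = unname(cf["t"]),
    sin = a, cos = b,
    amplitude = sqrt(a^2 + b^2),
    peak_month = which.max(seasonal),
    deviance = stats::deviance(fit),
    fitted = unname(stats::fitted(fit)),
    glm = fit
  ), class = "seasonal_fit")
}

#' @export
print.seasonal_fit <- function(x, ...) {
  cat("<seasonal_fit> log-linear Poisson, trend + first harmonic\n")
  cat(sprintf("  intercept %.4f, trend %.6f per month\n", x$intercept, x$trend))
  cat(sprintf("  seasonal amplitude %.4f (log scale), peak month %d\n",
              x$amplitude, x$peak_month))
  cat(sprintf("  residual deviance %.2f\n", x$deviance))
  invisible(x)
}
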