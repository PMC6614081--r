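# Internal helpers: named random streams, probability checks, date arithmetic.

causes_terminal <- function() c("community", "general_ward", "death")

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic sub-seed for a named random stream. Each generator concern
# (dates, causes, transfers, ...) draws under its own stream so that toggling
# one feature does not shift the draws of another.
stream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 104729L
  as.integer((as.numeric(seed) %% 20011) * 104729 + h)
}

with_stream <- function(seed, name, expr) {
  withr::with_seed(stream_seed(seed, name), expr)
}

assert_prob_vector <- function(p, field) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0)) {
    stop(sprintf("configuration error in `%s`: probabilities must be non-negative numbers", field),
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop(sprintf("configuration error in `%s`: probabilities sum to %.15f, not 1", field, sum(p)),
         call. = FALSE)
  }
  invisible(p)
}

assert_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("configuration error in `%s`: must be a single value in [0, 1]", field),
         call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("configuration error in `%s`: must be an integer >= %d", field, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

days_between <- function(from, to) as.integer(as.Date(to) - as.Date(from))

month_floor <- function(x) {
  x <- as.Date(x)
  as.Date(format(x, "%Y-%m-01"))
}

# Sequence of first-of-month dates covering [from, to].
month_seq <- function(from, to) {
  seq(month_floor(from), month_floor(to), by = "month")
}

days_in_month <- function(first_of_month) {
  nxt <- seq(first_of_month, by = "month", length.out = 2)[2]
  as.integer(nxt - first_of_month)
}
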