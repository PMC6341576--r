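# Shared numeric and date helpers.
#
# Conventions used throughout the package:
#   * all durations are whole days between calendar dates;
#   * 1 person-year  = 365 days;
#   * 1 person-month = 30.4375 days (365.25 / 12);
#   * age is the whole-year difference between two dates.

DAYS_PER_YEAR <- 365
DAYS_PER_MONTH <- 30.4375

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

#' Whole-day difference between two calendar dates
#' @param a,b `Date` vectors; the result is `a - b` in days.
#' @return Integer vector of day counts.
#' @keywords internal
days_between <- function(a, b) {
  as.integer(as_date(a)) - as.integer(as_date(b))
}

#' Age in completed years at a given date
#'
#' Whole-year difference: the age increments on the birthday anniversary.
#' @param birth_date,at_date `Date` vectors (recycled).
#' @return Integer ages.
#' @keywords internal
age_at <- function(birth_date, at_date) {
  b <- as.POSIXlt(as_date(birth_date))
  d <- as.POSIXlt(as_date(at_date))
  age <- d$year - b$year
  before_bday <- (d$mon < b$mon) | (d$mon == b$mon & d$mday < b$mday)
  as.integer(age - before_bday)
}

#' Round half away from zero
#'
#' Commercial rounding used when extrapolated stratum contributions are
#' converted to whole expected cases (0.05 * 353 = 17.65 -> 18). Base
#' `round()` rounds exact halves to the even digit (16.5 -> 16); the
#' half-away rule always rounds them up in magnitude.
#' @param x Numeric vector.
#' @return Numeric vector of integers.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param x Number of successes.
#' @param n Number of trials (`n >= 1`).
#' @param conf_level Coverage, default 0.95.
#' @return Numeric vector `c(low, high)` of proportions.
#' @examples
#' clopper_pearson(381, 400)
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  stopifnot(length(x) == 1, length(n) == 1, n >= 1, x >= 0, x <= n)
  alpha <- 1 - conf_level
  low <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(low = low, high = high)
}

# Log-normal CI for an event rate: exp(log(rate) +/- z/sqrt(events)).
# With zero events the exact upper Poisson bound 3.69/PT is used.
rate_ci <- function(events, person_time, scale, conf_level = 0.95) {
  stopifnot(person_time > 0)
  if (events == 0) {
    return(c(low = 0, high = 3.69 / person_time * scale))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  r <- events / person_time * scale
  f <- exp(z / sqrt(events))
  c(low = r / f, high = r * f)
}

stop_param <- function(...) {
  stop(structure(
    class = c("sclcehr_parameter_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_format <- function(...) {
  stop(structure(
    class = c("sclcehr_format_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_linkage <- function(...) {
  stop(structure(
    class = c("sclcehr_linkage_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_config <- function(...) {
  stop(structure(
    class = c("sclcehr_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

fmt_pct <- function(x, digits = 1) sprintf(paste0("%.", digits, "f"), x)
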