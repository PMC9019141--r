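#' Build a biweekly occasion calendar
#'
#' Discretizes a study of `n_years` study years into biweekly occasions.
#' A study year runs from the start of the breeding season (beginning of
#' May) to the end of the following April and is split into 26 fortnights:
#' the first 9 cover the breeding season (May-August, "BS") and the
#' remaining 17 the rest of the year (September-April, "REST").
#'
#' @param n_years Number of study years (>= 1).
#' @param start_year Calendar year label of the first study year (the year
#'   containing its May); defaults to 2009, the study's pilot year.
#' @return An object of class `occasion_calendar`: a list with elements
#'   `n_years`, `n_occasions` (= 26 * n_years), `period` (character vector
#'   "BS"/"REST" per occasion) and `year` (integer calendar-year label per
#'   occasion).
#' @examples
#' cal <- build_calendar(2)
#' table(cal$period) / cal$n_years
#' @export
build_calendar <- function(n_years, start_year = 2009L) {
  if (!is.numeric(n_years) || length(n_years) != 1L || is.na(n_years) ||
      n_years < 1 || n_years != round(n_years)) {
    stop("`n_years` must be a single integer >= 1", call. = FALSE)
  }
  n_years <- as.integer(n_years)
  per_year <- c(rep("BS", 9L), rep("REST", 17L))
  structure(
    list(
      n_years = n_years,
      occasions_per_year = 26L,
      n_occasions = 26L * n_years,
      period = rep(per_year, n_years),
      year = rep(as.integer(start_year) + seq_len(n_years) - 1L, each = 26L)
    ),
    class = "occasion_calendar"
  )
}

#' @export
print.occasion_calendar <- function(x, ...) {
  cat(sprintf(
    "Occasion calendar: %d study year(s) (%d-%d), %d biweekly occasions (9 BS + 17 REST per year)\n",
    x$n_years, x$year[1L], x$year[x$n_occasions], x$n_occasions
  ))
  invisible(x)
}

#' Period of an occasion
#'
#' @param calendar An `occasion_calendar`.
#' @param occasion Occasion index (1-based), vectorized.
#' @return "BS" or "REST" per occasion.
#' @export
period_of <- function(calendar, occasion) {
  check_occasion(calendar, occasion)
  calendar$period[occasion]
}

#' Calendar-year label of an occasion
#'
#' @inheritParams period_of
#' @return Integer calendar-year label per occasion.
#' @export
year_of <- function(calendar, occasion) {
  check_occasion(calendar, occasion)
  calendar$year[occasion]
}

check_occasion <- function(calendar, occasion) {
  if (!inherits(calendar, "occasion_calendar")) {
    stop("`calendar` must be an occasion_calendar", call. = FALSE)
  }
  if (any(is.na(occasion)) || any(occasion < 1L) ||
      any(occasion > calendar$n_occasions)) {
    stop(sprintf("occasion index out of range 1..%d", calendar$n_occasions),
         call. = FALSE)
  }
  invisible(TRUE)
}
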