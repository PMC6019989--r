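#' Gestational age in days
#'
#' Gestational age is stored throughout the package as integer days since the
#' last menstrual period (LMP). `ga_days()` converts the clinical
#' "X weeks Y days" notation, so `ga_days(7, 6)` (7 weeks 6 days) is 55 days
#' and `ga_days(8)` (8 weeks 0 days) is 56 days: the two are adjacent days,
#' never the same bin.
#'
#' @param weeks Completed weeks (non-negative integer).
#' @param days Additional days, 0--6.
#' @return Integer days since LMP.
#' @examples
#' ga_days(6)      # 42
#' ga_days(19, 6)  # 139, the last day before 20 weeks
#' @export
ga_days <- function(weeks, days = 0) {
  stopifnot(all(weeks >= 0), all(days >= 0), all(days <= 6))
  as.integer(7L * weeks + days)
}

#' Half-open gestational-age interval
#'
#' An interval `[start_days, end_days)` in days since LMP, the unit over which
#' loss rates are estimated. The week-labelled interval "a,0--b,6 weeks" maps
#' to `[7a, 7(b+1))` days: an event on the interval's first day belongs to it,
#' an event on `end_days` belongs to the next interval.
#'
#' @param start_days,end_days Integer day bounds, `0 <= start_days < end_days`.
#' @param label Optional display label; defaults to week notation.
#' @return An object of class `ga_interval`.
#' @seealso [canonical_intervals()]
#' @examples
#' ga_interval(ga_days(8), ga_days(12))  # "8,0-11,6 weeks"
#' @export
ga_interval <- function(start_days, end_days, label = NULL) {
  start_days <- as.integer(start_days); end_days <- as.integer(end_days)
  if (is.na(start_days) || is.na(end_days) || start_days < 0 || start_days >= end_days)
    stop("ga_interval requires 0 <= start_days < end_days")
  if (is.null(label)) {
    label <- sprintf("%d,%d-%d,%d weeks",
                     start_days %/% 7L, start_days %% 7L,
                     (end_days - 1L) %/% 7L, (end_days - 1L) %% 7L)
  }
  structure(list(start_days = start_days, end_days = end_days, label = label),
            class = "ga_interval")
}

#' @export
print.ga_interval <- function(x, ...) {
  cat(sprintf("<ga_interval> [%d, %d) days (%s)\n", x$start_days, x$end_days, x$label))
  invisible(x)
}

#' @export
format.ga_interval <- function(x, ...) x$label

#' Canonical study intervals
#'
#' The three gestational-age windows over which early loss rates are
#' estimated: 6,0--7,6 weeks (`[42, 56)` days), 8,0--11,6 weeks
#' (`[56, 84)` days) and 12,0--19,6 weeks (`[84, 140)` days). Day 140
#' (20 weeks 0 days) is the stillbirth boundary and the end of the
#' miscarriage/MTP window.
#'
#' @return A named list of three [ga_interval()] objects.
#' @export
canonical_intervals <- function() {
  list(
    ga_6_8   = ga_interval(ga_days(6),  ga_days(8)),
    ga_8_12  = ga_interval(ga_days(8),  ga_days(12)),
    ga_12_20 = ga_interval(ga_days(12), ga_days(20))
  )
}

# day marking the miscarriage/stillbirth boundary (20 weeks 0 days)
GA_20_WEEKS <- 140L
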