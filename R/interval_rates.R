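# Interval rate estimation under staggered enrollment (left truncation).
#
# A woman is "at risk" in [s, e) when she enrolled strictly before day s and
# had no loss (miscarriage or MTP) before day s.  Within the interval, each
# loss type's denominator excludes women experiencing the competing loss in
# the same interval, so a rate of r per 1000 means r events per 1000
# pregnancies still ongoing and not removed by the competing cause.

#' Build the risk set for a gestational-age interval
#'
#' Members enrolled strictly before the interval start and had no
#' miscarriage or MTP before it. Pregnancies still ongoing at the data cut
#' (no outcome recorded) are included; stillbirths and live births never
#' remove a woman from an early-loss risk set because they occur at or
#' after 20 weeks.
#'
#' @param records Registry data frame (pass through [exclude_unknown_ga()]
#'   first; rows with missing enrollment age are never members).
#' @param interval A [ga_interval()].
#' @return Object of class `risk_set`: list with `interval`, `member_ids`,
#'   `n`, and `members` (the member rows).
#' @export
build_risk_set <- function(records, interval) {
  stopifnot(inherits(interval, "ga_interval"))
  s <- interval$start_days
  lost_before <- !is.na(records$outcome) & records$outcome %in% LOSS_OUTCOMES &
    !is.na(records$outcome_ga_days) & records$outcome_ga_days < s
  member <- !is.na(records$enroll_ga_days) & records$enroll_ga_days < s & !lost_before
  members <- records[member, , drop = FALSE]
  rownames(members) <- NULL
  structure(list(interval = interval,
                 member_ids = as.character(members$woman_id),
                 n = nrow(members), members = members),
            class = "risk_set")
}

#' @export
print.risk_set <- function(x, ...) {
  cat(sprintf("<risk_set> %s: %d pregnancies at risk\n", x$interval$label, x$n))
  invisible(x)
}

#' Count loss events of one type inside an interval
#'
#' Counts risk-set members whose recorded outcome is `event` with
#' `start_days <= outcome_ga_days < end_days` (half-open, so an event on the
#' interval's end day belongs to the next interval).
#'
#' @inheritParams build_risk_set
#' @param event `"MISCARRIAGE"` or `"MTP"`.
#' @return Integer count.
#' @export
count_interval_events <- function(records, interval, event) {
  event <- match.arg(event, LOSS_OUTCOMES)
  rs <- build_risk_set(records, interval)
  m <- rs$members
  sum(!is.na(m$outcome) & m$outcome == event &
        !is.na(m$outcome_ga_days) &
        m$outcome_ga_days >= interval$start_days &
        m$outcome_ga_days < interval$end_days)
}

competing_event <- function(event) {
  if (event == "MISCARRIAGE") "MTP" else "MISCARRIAGE"
}

#' Per-1000 loss rate in a gestational-age interval
#'
#' The denominator is the risk-set size minus the number of competing-type
#' losses in the same interval: the miscarriage denominator excludes the
#' interval's MTPs and vice versa, so each rate is per 1000 pregnancies not
#' removed by the competing cause.
#'
#' @inheritParams count_interval_events
#' @return List with `numerator`, `denominator`, `rate_per_1000` (full
#'   precision; display rounds to one decimal).
#' @export
interval_rate <- function(records, interval, event) {
  event <- match.arg(event, LOSS_OUTCOMES)
  rs <- build_risk_set(records, interval)
  n_event <- count_interval_events(records, interval, event)
  n_comp  <- count_interval_events(records, interval, competing_event(event))
  den <- rs$n - n_comp
  if (den == 0)
    stop(sprintf("zero denominator for %s in %s (risk set %d, competing events %d)",
                 event, interval$label, rs$n, n_comp))
  list(numerator = n_event, denominator = den,
       rate_per_1000 = per_1000(n_event, den))
}

#' Per-1000 rate from a numerator and denominator
#'
#' @param numerator,denominator Event count and at-risk count.
#' @return `1000 * numerator / denominator` at full precision.
#' @export
per_1000 <- function(numerator, denominator) 1000 * numerator / denominator

#' Interval-by-event loss rate table
#'
#' Applies [interval_rate()] to each interval and both loss types,
#' producing the per-1000 rate table that drives [project_cohort()].
#'
#' @param records Registry data frame.
#' @param intervals List of [ga_interval()]s; defaults to
#'   [canonical_intervals()].
#' @return Data frame of class `interval_rate_table` with columns
#'   `interval`, `start_days`, `end_days`, `event`, `n_event`, `n_at_risk`,
#'   `rate_per_1000`, plus attribute `risk_set_n` (per-interval risk-set
#'   sizes before competing-event exclusion).
#' @export
rate_table <- function(records, intervals = canonical_intervals()) {
  rows <- list(); rs_n <- integer(0)
  for (iv in intervals) {
    rs_n <- c(rs_n, build_risk_set(records, iv)$n)
    for (ev in LOSS_OUTCOMES) {
      r <- interval_rate(records, iv, ev)
      rows[[length(rows) + 1]] <- data.frame(
        interval = iv$label, start_days = iv$start_days, end_days = iv$end_days,
        event = ev, n_event = r$numerator, n_at_risk = r$denominator,
        rate_per_1000 = r$rate_per_1000, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "risk_set_n") <- rs_n
  class(out) <- c("interval_rate_table", "data.frame")
  out
}

#' @export
print.interval_rate_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$rate_per_1000 <- sprintf("%.1f", y$rate_per_1000)
  print(y[c("interval", "event", "n_event", "n_at_risk", "rate_per_1000")],
        row.names = FALSE)
  invisible(x)
}
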