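# Multiple-decrement projection of a closed hypothetical cohort: interval
# loss rates are applied sequentially to the pregnancies still ongoing, then
# post-20-week terminations, stillbirths and neonatal deaths are removed to
# give live infants at 28 days.

round_policy <- function(rounding = c("nearest", "floor", "none")) {
  rounding <- match.arg(rounding)
  switch(rounding,
         nearest = function(x) trunc(x + 0.5),  # half away from zero
         floor   = floor,
         none    = identity)
}

#' Apply one interval's loss rates to an ongoing cohort
#'
#' Miscarriage and MTP decrements are computed simultaneously from the same
#' entering count (`entering * rate / 1000`, each rounded under `rounding`),
#' matching a rate convention in which each cause's per-1000 rate already
#' excludes the competing cause from its denominator.
#'
#' @param entering Pregnancies ongoing at the interval start.
#' @param misc_rate_per_1000,mtp_rate_per_1000 Interval loss rates per 1000.
#' @param rounding `"nearest"` (default; half away from zero), `"floor"`, or
#'   `"none"` for a continuous projection.
#' @param label Step label.
#' @return One-row data frame with `label`, `entering`, `miscarriages`,
#'   `mtps`, `stillbirths`, `neonatal_deaths`, `exiting`.
#' @examples
#' project_interval(1000, 115.3, 45.4)  # 115 miscarriages, 45 MTPs, 840 exit
#' @export
project_interval <- function(entering, misc_rate_per_1000, mtp_rate_per_1000,
                             rounding = "nearest", label = "interval") {
  stopifnot(entering >= 0, misc_rate_per_1000 >= 0, mtp_rate_per_1000 >= 0)
  rnd <- round_policy(rounding)
  misc <- rnd(entering * misc_rate_per_1000 / 1000)
  mtp  <- rnd(entering * mtp_rate_per_1000 / 1000)
  if (misc + mtp > entering)
    stop(sprintf("decrements (%s + %s) exceed entering count %s in step '%s'",
                 format(misc), format(mtp), format(entering), label))
  data.frame(label = label, entering = entering, miscarriages = misc,
             mtps = mtp, stillbirths = 0, neonatal_deaths = 0,
             exiting = entering - misc - mtp, stringsAsFactors = FALSE)
}

#' Project a hypothetical cohort through the early-loss intervals
#'
#' Starting from `initial_n` pregnancies ongoing at the first interval's
#' start (6 weeks for the canonical intervals), applies each interval's
#' miscarriage and MTP rates in order; each step's entering count is the
#' previous step's exiting count.
#'
#' @param rates An `interval_rate_table` from [rate_table()], or any data
#'   frame with `interval`, `start_days`, `event`, `rate_per_1000`.
#' @param initial_n Cohort size at the first interval start (default 1000).
#' @inheritParams project_interval
#' @return Object of class `cohort_projection`: list with `initial_n`,
#'   `rounding`, `steps` (data frame of decrement steps) and `alive_at_28d`
#'   (`NA` until [extend_perinatal()] is applied).
#' @export
project_cohort <- function(rates, initial_n = 1000, rounding = "nearest") {
  stopifnot(is.data.frame(rates),
            all(c("interval", "start_days", "event", "rate_per_1000") %in% names(rates)))
  labs <- unique(rates$interval[order(rates$start_days)])
  steps <- list()
  ongoing <- initial_n
  for (lab in labs) {
    sub <- rates[rates$interval == lab, ]
    pick <- function(ev) {
      r <- sub$rate_per_1000[sub$event == ev]
      if (length(r) != 1) stop("rate table lacks a unique ", ev, " rate for interval ", lab)
      r
    }
    st <- project_interval(ongoing, pick("MISCARRIAGE"), pick("MTP"),
                           rounding = rounding, label = lab)
    steps[[length(steps) + 1]] <- st
    ongoing <- st$exiting
  }
  structure(list(initial_n = initial_n, rounding = rounding,
                 steps = do.call(rbind, steps), alive_at_28d = NA_real_),
            class = "cohort_projection")
}

#' Extend a projection through stillbirth and neonatal mortality
#'
#' From the pregnancies ongoing at 20 weeks, removes a fixed count of
#' post-20-week MTPs (reported as a count, not a rate), then applies the
#' stillbirth rate to the remaining pregnancies and the neonatal mortality
#' rate to the resulting live births, yielding infants alive at 28 days.
#'
#' @param projection A `cohort_projection` from [project_cohort()].
#' @param sb_per_1000 Stillbirth rate per 1000 ongoing pregnancies at
#'   20 weeks (default 26).
#' @param nmr_per_1000 28-day neonatal mortality rate per 1000 live births
#'   (default 24).
#' @param post20_mtp Absolute count of MTPs after 20 weeks (default 2).
#' @param rounding Rounding policy; defaults to the projection's own.
#' @return The projection with three further steps and `alive_at_28d` set.
#' @export
extend_perinatal <- function(projection, sb_per_1000 = 26, nmr_per_1000 = 24,
                             post20_mtp = 2, rounding = projection$rounding) {
  stopifnot(inherits(projection, "cohort_projection"))
  rnd <- round_policy(rounding)
  ongoing <- projection$steps$exiting[nrow(projection$steps)]
  if (post20_mtp > ongoing)
    stop("post-20-week MTP count exceeds ongoing pregnancies at 20 weeks")
  remaining <- ongoing - post20_mtp
  sb <- rnd(remaining * sb_per_1000 / 1000)
  if (sb > remaining) stop("stillbirth decrement exceeds remaining pregnancies")
  live <- remaining - sb
  nd <- rnd(live * nmr_per_1000 / 1000)
  if (nd > live) stop("neonatal-death decrement exceeds live births")
  extra <- data.frame(
    label = c("post-20w MTP", "stillbirth", "neonatal death"),
    entering = c(ongoing, remaining, live),
    miscarriages = 0, mtps = c(post20_mtp, 0, 0),
    stillbirths = c(0, sb, 0), neonatal_deaths = c(0, 0, nd),
    exiting = c(remaining, live, live - nd), stringsAsFactors = FALSE)
  projection$steps <- rbind(projection$steps, extra)
  projection$alive_at_28d <- live - nd
  projection
}

#' Render a projection as a flow table
#'
#' One row per decrement step plus a final row for infants alive at
#' 28 days; the sum of all decrements and the final count reproduces the
#' initial cohort size (conservation).
#'
#' @param projection A `cohort_projection`.
#' @return Data frame with the step columns of [project_interval()].
#' @export
render_projection <- function(projection) {
  stopifnot(inherits(projection, "cohort_projection"))
  steps <- projection$steps
  if (is.null(steps) || nrow(steps) == 0)
    return(data.frame(label = character(0), entering = numeric(0),
                      miscarriages = numeric(0), mtps = numeric(0),
                      stillbirths = numeric(0), neonatal_deaths = numeric(0),
                      exiting = numeric(0), stringsAsFactors = FALSE))
  final <- steps$exiting[nrow(steps)]
  rbind(steps, data.frame(label = "alive at 28 days", entering = final,
                          miscarriages = 0, mtps = 0, stillbirths = 0,
                          neonatal_deaths = 0, exiting = final,
                          stringsAsFactors = FALSE))
}

#' @export
print.cohort_projection <- function(x, ...) {
  cat(sprintf("<cohort_projection> initial %s pregnancies, rounding '%s'\n",
              format(x$initial_n), x$rounding))
  print(render_projection(x), row.names = FALSE)
  if (!is.na(x$alive_at_28d))
    cat(sprintf("alive at 28 days: %s\n", format(x$alive_at_28d)))
  invisible(x)
}
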