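# Synthetic pregnancy registry generator.
#
# Emulates the statistical structure the estimators assume: staggered
# enrollment across gestational-age bands, interval-specific competing loss
# draws (one categorical draw per woman per interval: miscarriage / MTP /
# survive), multiplicative covariate and cluster effects on loss risk,
# perinatal stillbirth and neonatal-death draws, and a small fraction of
# records with the enrollment gestational age blanked.  Every draw is
# recorded in a ground-truth table so estimator output can be checked
# against what was planted.

# enrollment day ranges (inclusive) for the five enrollment-timing bands
ENROLL_BANDS <- list(
  pre6   = c(28L, 41L),
  w6_8   = c(42L, 55L),
  w8_12  = c(56L, 83L),
  w12_20 = c(84L, 139L),
  ge20   = c(140L, 195L)
)

#' Synthetic registry configuration
#'
#' Defaults emulate the source registry's published structure: the
#' enrollment-timing distribution (9.2 / 28.9 / 36.4 / 19.9 / 5.6 percent
#' before 6 weeks, 6--8, 8--12, 12--20, and at/after 20 weeks), the
#' per-interval per-1000 loss-rate targets (miscarriage 115.3 / 101.9 /
#' 60.3 and MTP 45.4 / 48.3 / 40.2), a stillbirth rate of 26 and 28-day
#' neonatal mortality of 24 per 1000, 2.2 percent missing enrollment
#' gestational age, and care-descriptor probabilities per outcome group.
#' Covariate marginals are simple parametric choices (see the package
#' vignette); covariate effects default to null (all relative risks 1).
#'
#' Loss-rate targets are interpreted under the same competing-event
#' denominator-exclusion convention as the estimator: the per-woman
#' categorical probabilities (q_misc, q_mtp) are solved from the targets
#' (p_m, p_t) via `q_m = p_m (1 - p_t) / (1 - p_m p_t)` and symmetrically,
#' so the estimated rates are unbiased for the configured targets.
#'
#' @param n_women Number of pregnancies to simulate.
#' @param n_clusters Number of study clusters.
#' @param enrollment_dist Probabilities over the five enrollment bands
#'   `pre6, w6_8, w8_12, w12_20, ge20`; must sum to 1.
#' @param interval_loss_rates 3x2 matrix of per-1000 targets, rows the
#'   canonical intervals in order, columns `MISCARRIAGE`, `MTP`.
#' @param covariate_rr Named list with elements `MISCARRIAGE` and `MTP`,
#'   each a named numeric vector of multiplicative effects keyed as
#'   `"factor:level"` (e.g. `c("age_cat:GT30" = 2.19)`); unnamed levels
#'   have effect 1.
#' @param cluster_sd Standard deviation of cluster log-risk intercepts;
#'   intercepts are drawn with mean `-cluster_sd^2/2` on the log scale so
#'   the multiplicative cluster effect has mean 1.
#' @param sb_per_1000,nmr_per_1000 Stillbirth rate per 1000 pregnancies
#'   ongoing at 20 weeks and neonatal mortality per 1000 live births.
#' @param missing_ga_frac Fraction of records whose enrollment gestational
#'   age is blanked (these are removed by [exclude_unknown_ga()]).
#' @param covariate_dists Overrides for covariate marginals; see the
#'   returned object's `covariate_dists` element for the knobs.
#' @param care_probs Overrides for per-group ANC-band, attendant and
#'   location probabilities.
#' @param seed Default seed used by [generate_registry()] when none is
#'   passed explicitly.
#' @return A list of class `registry_config`.
#' @export
registry_config <- function(n_women = 30000,
                            n_clusters = 20,
                            enrollment_dist = c(pre6 = 0.092, w6_8 = 0.289,
                                                w8_12 = 0.364, w12_20 = 0.199,
                                                ge20 = 0.056),
                            interval_loss_rates = NULL,
                            covariate_rr = list(MISCARRIAGE = numeric(0),
                                                MTP = numeric(0)),
                            cluster_sd = 0.15,
                            sb_per_1000 = 26,
                            nmr_per_1000 = 24,
                            missing_ga_frac = 0.022,
                            covariate_dists = list(),
                            care_probs = list(),
                            seed = NULL) {
  if (is.null(interval_loss_rates)) {
    interval_loss_rates <- matrix(c(115.3, 45.4,
                                    101.9, 48.3,
                                    60.3, 40.2),
                                  nrow = 3, byrow = TRUE,
                                  dimnames = list(names(canonical_intervals()),
                                                  c("MISCARRIAGE", "MTP")))
  }
  stopifnot(n_women >= 0, n_clusters >= 1,
            length(enrollment_dist) == 5,
            abs(sum(enrollment_dist) - 1) < 1e-8,
            all(interval_loss_rates >= 0), all(interval_loss_rates <= 1000),
            cluster_sd >= 0, missing_ga_frac >= 0, missing_ga_frac < 1)
  cd <- utils::modifyList(list(
    age_mean = 23.5, age_sd = 4, age_range = c(16L, 45L),
    education_probs = c(NONE = 0.15, PRIMARY = 0.25,
                        SECONDARY = 0.50, UNIVERSITY_PLUS = 0.10),
    parity_lambda = 1.1,
    weight_mean = 50, weight_sd = 7, weight_min = 32,
    height_mean = 1.55, height_sd = 0.06, height_range = c(1.35, 1.85),
    hb_mean = 10.8, hb_sd = 1.5, hb_range = c(4, 17), hb_missing_frac = 0.05
  ), covariate_dists)
  cp <- utils::modifyList(list(
    anc_band = list(  # P(0 visits, 1-2 visits, >2 visits) per outcome group
      MISCARRIAGE = c(0.061, 0.930, 0.009),
      MTP         = c(0.048, 0.914, 0.038),
      ONGOING_20W = c(0.000, 0.052, 0.948)),
    attendant = list(  # physician, nurse/midwife, TBA, family/self/other
      MISCARRIAGE = c(0.026, 0.007, 0.001, 0.966),
      MTP         = c(0.848, 0.012, 0.007, 0.132),
      ONGOING_20W = c(0.611, 0.358, 0.004, 0.027)),
    location = list(   # hospital, clinic/health center, home/other
      MISCARRIAGE = c(0.028, 0.009, 0.963),
      MTP         = c(0.696, 0.097, 0.207),
      ONGOING_20W = c(0.713, 0.243, 0.044))
  ), care_probs)
  structure(list(n_women = as.integer(n_women), n_clusters = as.integer(n_clusters),
                 enrollment_dist = enrollment_dist,
                 interval_loss_rates = interval_loss_rates,
                 covariate_rr = covariate_rr, cluster_sd = cluster_sd,
                 sb_per_1000 = sb_per_1000, nmr_per_1000 = nmr_per_1000,
                 missing_ga_frac = missing_ga_frac,
                 covariate_dists = cd, care_probs = cp, seed = seed),
            class = "registry_config")
}

# categorical probabilities (q_misc, q_mtp) whose denominator-exclusion
# estimand equals the per-1000 targets
loss_draw_probs <- function(rate_misc_per_1000, rate_mtp_per_1000) {
  pm <- unname(rate_misc_per_1000) / 1000
  pt <- unname(rate_mtp_per_1000) / 1000
  denom <- 1 - pm * pt
  c(misc = pm * (1 - pt) / denom, mtp = pt * (1 - pm) / denom)
}

# per-woman multiplicative effect for one event from "factor:level" keys
covariate_multiplier <- function(profile, rr) {
  mult <- rep(1, nrow(profile))
  if (!length(rr)) return(mult)
  keys <- strsplit(names(rr), ":", fixed = TRUE)
  for (i in seq_along(rr)) {
    f <- keys[[i]][1]; lev <- keys[[i]][2]
    if (!f %in% names(profile))
      stop("covariate_rr names unknown factor: ", f)
    hit <- !is.na(profile[[f]]) & profile[[f]] == lev
    mult[hit] <- mult[hit] * rr[[i]]
  }
  mult
}

#' Generate a synthetic registry with ground truth
#'
#' Draws one pregnancy per woman under the configuration's enrollment,
#' loss, covariate-effect and cluster-heterogeneity structure, then emits
#' the registry records alongside a ground-truth table recording every
#' planted quantity. Identical `(config, seed)` pairs give identical
#' output.
#'
#' Each woman is at risk in a canonical interval only if she enrolled
#' strictly before its start; losses are drawn only in at-risk intervals,
#' so a simulated loss can never predate enrollment and women enrolling
#' mid-interval first contribute to the following interval — the same
#' convention the estimator uses.
#'
#' @param config A [registry_config()].
#' @param seed Integer seed; falls back to `config$seed`, else 1.
#' @return List with `records` (registry data frame), `truth` (list with
#'   per-woman data frame `women`, per-interval planted totals
#'   `per_interval`, and the `config`).
#' @export
generate_registry <- function(config = registry_config(), seed = config$seed) {
  stopifnot(inherits(config, "registry_config"))
  if (is.null(seed)) seed <- 1L
  set.seed(as.integer(seed))
  n <- config$n_women
  intervals <- canonical_intervals()
  if (n == 0) {
    rec <- empty_registry()
    truth <- list(women = data.frame(), per_interval = data.frame(), config = config)
    return(list(records = rec, truth = truth))
  }
  cd <- config$covariate_dists
  cluster_idx <- sample.int(config$n_clusters, n, replace = TRUE)
  cluster_log <- stats::rnorm(config$n_clusters,
                              mean = -config$cluster_sd^2 / 2,
                              sd = config$cluster_sd)
  cluster_eff <- exp(cluster_log)[cluster_idx]

  age <- pmin(pmax(round(stats::rnorm(n, cd$age_mean, cd$age_sd)),
                   cd$age_range[1]), cd$age_range[2])
  education <- sample(names(cd$education_probs), n, TRUE, cd$education_probs)
  parity <- stats::rpois(n, cd$parity_lambda)
  weight <- pmax(stats::rnorm(n, cd$weight_mean, cd$weight_sd), cd$weight_min)
  height <- pmin(pmax(stats::rnorm(n, cd$height_mean, cd$height_sd),
                      cd$height_range[1]), cd$height_range[2])
  hb <- pmin(pmax(stats::rnorm(n, cd$hb_mean, cd$hb_sd), cd$hb_range[1]),
             cd$hb_range[2])
  hb[stats::runif(n) < cd$hb_missing_frac] <- NA_real_

  band <- sample(names(ENROLL_BANDS), n, TRUE, config$enrollment_dist)
  enroll <- integer(n)
  for (b in names(ENROLL_BANDS)) {
    idx <- band == b
    r <- ENROLL_BANDS[[b]]
    enroll[idx] <- sample(r[1]:r[2], sum(idx), replace = TRUE)
  }

  profile <- categorize(data.frame(
    woman_id = seq_len(n), maternal_age_years = age, education = education,
    parity = parity, weight_kg = weight, height_m = height,
    hemoglobin_g_dl = hb, stringsAsFactors = FALSE))
  rr_misc <- covariate_multiplier(profile, config$covariate_rr$MISCARRIAGE)
  rr_mtp  <- covariate_multiplier(profile, config$covariate_rr$MTP)

  event <- rep("NONE", n)
  loss_interval <- rep(NA_character_, n)
  outcome_ga <- rep(NA_integer_, n)
  for (k in seq_along(intervals)) {
    iv <- intervals[[k]]
    base <- loss_draw_probs(config$interval_loss_rates[k, "MISCARRIAGE"],
                            config$interval_loss_rates[k, "MTP"])
    at_risk <- enroll < iv$start_days & event == "NONE"
    pm <- base["misc"] * rr_misc * cluster_eff
    pt <- base["mtp"] * rr_mtp * cluster_eff
    over <- at_risk & (pm + pt > 1)
    if (any(over)) {
      i <- which(over)[1]
      lev <- offending_levels(profile[i, ], config$covariate_rr)
      stop(sprintf(
        "loss probability exceeds 1 in %s (misc %.3f + mtp %.3f); offending level(s): %s",
        iv$label, pm[i], pt[i], lev))
    }
    u <- stats::runif(n)
    misc_hit <- at_risk & u < pm
    mtp_hit  <- at_risk & !misc_hit & u < pm + pt
    hit <- misc_hit | mtp_hit
    event[misc_hit] <- "MISCARRIAGE"
    event[mtp_hit]  <- "MTP"
    loss_interval[hit] <- iv$label
    outcome_ga[hit] <- sample(iv$start_days:(iv$end_days - 1L),
                              sum(hit), replace = TRUE)
  }

  survivors <- event == "NONE"
  sb_hit <- survivors & stats::runif(n) < config$sb_per_1000 / 1000
  event[sb_hit] <- "STILLBIRTH"
  outcome_ga[sb_hit] <- pmax(enroll[sb_hit] + 1L,
                             sample(140:293, sum(sb_hit), replace = TRUE))
  live <- event == "NONE"
  event[live] <- "LIVEBIRTH"
  outcome_ga[live] <- pmax(enroll[live] + 1L,
                           sample(259:293, sum(live), replace = TRUE))
  neo_death <- rep(NA, n)
  neo_death[live] <- stats::runif(sum(live)) < config$nmr_per_1000 / 1000

  group <- ifelse(event %in% LOSS_OUTCOMES, event, "ONGOING_20W")
  anc_visits <- integer(n); attendant <- character(n); location <- character(n)
  cp <- config$care_probs
  for (g in OUTCOME_GROUPS) {
    idx <- which(group == g)
    if (!length(idx)) next
    bandx <- sample(c("0", "1-2", ">2"), length(idx), TRUE,
                    cp$anc_band[[g]] / sum(cp$anc_band[[g]]))
    anc_visits[idx] <- ifelse(bandx == "0", 0L,
                       ifelse(bandx == "1-2", sample(1:2, length(idx), TRUE),
                              sample(3:8, length(idx), TRUE)))
    attendant[idx] <- sample(ATTENDANT_LEVELS, length(idx), TRUE,
                             cp$attendant[[g]] / sum(cp$attendant[[g]]))
    location[idx] <- sample(LOCATION_LEVELS, length(idx), TRUE,
                            cp$location[[g]] / sum(cp$location[[g]]))
  }

  ga_missing <- stats::runif(n) < config$missing_ga_frac
  woman_id <- sprintf("W%06d", seq_len(n))
  cluster_id <- sprintf("C%03d", cluster_idx)

  records <- data.frame(
    woman_id = woman_id, cluster_id = cluster_id,
    enroll_ga_days = ifelse(ga_missing, NA_integer_, enroll),
    outcome = event, outcome_ga_days = outcome_ga,
    neonatal_death_by_28d = neo_death,
    maternal_age_years = age, education = education, parity = parity,
    weight_kg = round(weight, 1), height_m = round(height, 2),
    hemoglobin_g_dl = round(hb, 1), anc_visits = anc_visits,
    attendant = attendant, location = location, stringsAsFactors = FALSE)

  women <- data.frame(
    woman_id = woman_id, cluster_id = cluster_id, band = band,
    enroll_ga_days = enroll, ga_missing = ga_missing, event = event,
    loss_interval = loss_interval, outcome_ga_days = outcome_ga,
    rr_misc = rr_misc, rr_mtp = rr_mtp, cluster_effect = cluster_eff,
    neonatal_death = neo_death, stringsAsFactors = FALSE)
  per_interval <- planted_totals(women, intervals)
  list(records = records,
       truth = list(women = women, per_interval = per_interval, config = config))
}

offending_levels <- function(profile_row, covariate_rr) {
  out <- character(0)
  for (ev in names(covariate_rr)) {
    rr <- covariate_rr[[ev]]
    if (!length(rr)) next
    keys <- strsplit(names(rr), ":", fixed = TRUE)
    for (i in seq_along(rr)) {
      f <- keys[[i]][1]; lev <- keys[[i]][2]
      if (!is.na(profile_row[[f]]) && profile_row[[f]] == lev && rr[[i]] > 1)
        out <- c(out, sprintf("%s=%s (%s RR %.2f)", f, lev, ev, rr[[i]]))
    }
  }
  if (!length(out)) "cluster effect only" else paste(unique(out), collapse = "; ")
}

planted_totals <- function(women, intervals) {
  rows <- list()
  for (iv in intervals) for (ev in LOSS_OUTCOMES) {
    cnt <- sum(women$event == ev & !is.na(women$loss_interval) &
                 women$loss_interval == iv$label)
    rows[[length(rows) + 1]] <- data.frame(
      interval = iv$label, event = ev, planted = cnt, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_registry <- function() {
  cols <- names(REGISTRY_COLUMNS)
  out <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)), cols))
  out
}

#' Realized per-1000 rate from generator ground truth
#'
#' Recomputes the interval rate from the ground-truth table alone (true
#' enrollment days and planted events, excluding women whose emitted record
#' had the enrollment gestational age blanked), using the same risk-set and
#' denominator-exclusion convention as [interval_rate()]. On the emitted
#' records the two agree exactly; the truth table simply bypasses the
#' registry I/O path.
#'
#' @param truth The `truth` element returned by [generate_registry()].
#' @param interval A [ga_interval()].
#' @param event `"MISCARRIAGE"` or `"MTP"`.
#' @return List with `numerator`, `denominator`, `rate_per_1000` (0 when
#'   no planted events; errors on an empty denominator).
#' @export
truth_rate <- function(truth, interval, event) {
  event <- match.arg(event, LOSS_OUTCOMES)
  w <- truth$women
  if (!nrow(w))
    return(list(numerator = 0L, denominator = 0L, rate_per_1000 = NaN))
  w <- w[!w$ga_missing, , drop = FALSE]
  s <- interval$start_days
  lost_before <- w$event %in% LOSS_OUTCOMES & !is.na(w$outcome_ga_days) &
    w$outcome_ga_days < s
  member <- w$enroll_ga_days < s & !lost_before
  m <- w[member, , drop = FALSE]
  in_iv <- function(ev) sum(m$event == ev & !is.na(m$outcome_ga_days) &
                              m$outcome_ga_days >= s &
                              m$outcome_ga_days < interval$end_days)
  num <- in_iv(event)
  den <- nrow(m) - in_iv(competing_event(event))
  if (den == 0) stop("zero truth denominator for ", event, " in ", interval$label)
  list(numerator = num, denominator = den, rate_per_1000 = per_1000(num, den))
}
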