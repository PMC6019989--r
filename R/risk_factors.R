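# Risk-factor relative risks: maternal covariates are categorized with the
# registry's standard cut points, then each loss type in each interval is
# contrasted against pregnancies ongoing at the interval end in a log-link
# binomial model with all five covariate factors plus a cluster random
# intercept; exponentiated coefficients are adjusted relative risks.

AGE_LEVELS    <- c("A21_25", "LE20", "A26_30", "GT30")        # ref first
EDU_MODEL_LEVELS <- c("PRIMARY", "NONE", "SECONDARY", "UNIVERSITY_PLUS")
PARITY_LEVELS <- c("P1_2", "P0", "GT2")
BMI_LEVELS    <- c("NORMAL_18_5_25", "UNDER_18_5", "OVER_25")
HB_LEVELS     <- c("NORMAL_GT11", "SEV_MOD_LE9", "MILD_9_11")

COVARIATE_FACTORS <- c("age_cat", "education_cat", "parity_cat", "bmi_cat", "hb_cat")

#' Categorize maternal covariates
#'
#' Maps raw covariates to the analysis categories, reference level first:
#' age <=20 / 21--25 (ref) / 26--30 / >30 years; education none / primary
#' (ref) / secondary / university+; parity 0 / 1--2 (ref) / >2; BMI
#' (weight_kg / height_m^2) <18.5 / 18.5--25 (ref, both bounds included) /
#' >25 kg/m^2; hemoglobin <=9 (severe/moderate anemia) / >9--11 (mild) /
#' >11 g/dl (ref). Missing inputs yield `NA` categories; model fits are
#' complete-case.
#'
#' @param records Registry data frame.
#' @return Data frame with factor columns `age_cat`, `education_cat`,
#'   `parity_cat`, `bmi_cat`, `hb_cat` and numeric `bmi`, row-aligned with
#'   `records`.
#' @export
categorize <- function(records) {
  bad_hw <- (!is.na(records$weight_kg) & records$weight_kg <= 0) |
    (!is.na(records$height_m) & records$height_m <= 0)
  if (any(bad_hw))
    stop("non-positive weight/height for woman_id: ",
         paste(utils::head(records$woman_id[bad_hw], 5), collapse = ", "))
  age <- records$maternal_age_years
  age_cat <- ifelse(is.na(age), NA_character_,
             ifelse(age <= 20, "LE20",
             ifelse(age <= 25, "A21_25",
             ifelse(age <= 30, "A26_30", "GT30"))))
  par <- records$parity
  parity_cat <- ifelse(is.na(par), NA_character_,
                ifelse(par == 0, "P0", ifelse(par <= 2, "P1_2", "GT2")))
  bmi <- records$weight_kg / records$height_m^2
  bmi_cat <- ifelse(is.na(bmi), NA_character_,
             ifelse(bmi < 18.5, "UNDER_18_5",
             ifelse(bmi <= 25, "NORMAL_18_5_25", "OVER_25")))
  hb <- records$hemoglobin_g_dl
  hb_cat <- ifelse(is.na(hb), NA_character_,
            ifelse(hb <= 9, "SEV_MOD_LE9",
            ifelse(hb <= 11, "MILD_9_11", "NORMAL_GT11")))
  data.frame(
    age_cat = factor(age_cat, levels = AGE_LEVELS),
    education_cat = factor(records$education, levels = EDU_MODEL_LEVELS),
    parity_cat = factor(parity_cat, levels = PARITY_LEVELS),
    bmi_cat = factor(bmi_cat, levels = BMI_LEVELS),
    hb_cat = factor(hb_cat, levels = HB_LEVELS),
    bmi = bmi, stringsAsFactors = FALSE)
}

#' Cases and ongoing-pregnancy comparisons for one interval and loss type
#'
#' Within the interval's risk set, cases are members with the given loss in
#' the interval; comparisons are members whose pregnancy was still ongoing
#' at the interval end (no loss recorded before `end_days`). Members lost
#' to the competing cause in the interval belong to neither group,
#' mirroring the denominator-exclusion rate convention.
#'
#' @inheritParams count_interval_events
#' @return List with data frames `cases` and `comparisons`, plus
#'   `interval` and `event`.
#' @export
build_comparison_set <- function(records, interval, event) {
  event <- match.arg(event, LOSS_OUTCOMES)
  rs <- build_risk_set(records, interval)
  m <- rs$members
  in_interval <- !is.na(m$outcome) & m$outcome %in% LOSS_OUTCOMES &
    !is.na(m$outcome_ga_days) &
    m$outcome_ga_days >= interval$start_days &
    m$outcome_ga_days < interval$end_days
  is_case <- in_interval & m$outcome == event
  lost_by_end <- !is.na(m$outcome) & m$outcome %in% LOSS_OUTCOMES &
    !is.na(m$outcome_ga_days) & m$outcome_ga_days < interval$end_days
  is_comparison <- !lost_by_end
  list(cases = m[is_case, , drop = FALSE],
       comparisons = m[is_comparison, , drop = FALSE],
       interval = interval, event = event)
}

#' Fit an adjusted log-binomial relative-risk model
#'
#' Stacks cases and comparisons, categorizes covariates and fits
#' `event ~ age + education + parity + BMI + hemoglobin + (1 | cluster)`
#' with a binomial family and log link, so exponentiated coefficients are
#' adjusted relative risks versus each factor's reference level. The
#' cluster random intercept is integrated out by Laplace approximation
#' (glmmTMB); with fewer than two clusters the model falls back to a
#' fixed-intercept log-binomial `glm` with a warning. Rows with any missing
#' model covariate are dropped (complete case). Non-convergence is reported
#' in the result, never silently.
#'
#' @param cases,comparisons Registry data frames as returned by
#'   [build_comparison_set()].
#' @param interval,event Labels carried into the result.
#' @return Object of class `rr_result`: data frame `estimates` with one row
#'   per factor level (`covariate`, `level`, `rr`, `ci_low`, `ci_high`,
#'   `is_ref`), counts `n_cases`, `n_comparison`, `n_model` (complete-case
#'   rows), `cluster_sd`, and flags `converged`, `random_effect`,
#'   `messages`.
#' @export
fit_rr <- function(cases, comparisons, interval = NULL, event = NULL) {
  if (is.list(cases) && !is.data.frame(cases) && all(c("cases", "comparisons") %in% names(cases))) {
    cs <- cases
    comparisons <- cs$comparisons
    if (is.null(interval)) interval <- cs$interval
    if (is.null(event)) event <- cs$event
    cases <- cs$cases
  }
  if (nrow(cases) < 2 || nrow(comparisons) < 2)
    stop(sprintf("fit refused: %d case(s) and %d comparison(s); need at least 2 of each",
                 nrow(cases), nrow(comparisons)))
  d <- rbind(cases, comparisons)
  d$.case <- rep(c(1L, 0L), c(nrow(cases), nrow(comparisons)))
  cov <- categorize(d)
  d <- cbind(d[c(".case", "cluster_id")], cov[COVARIATE_FACTORS])
  cc <- stats::complete.cases(d)
  d <- d[cc, , drop = FALSE]
  if (sum(d$.case) < 2 || sum(1 - d$.case) < 2)
    stop("fit refused: fewer than 2 cases or comparisons after complete-case filtering")
  drop_const <- vapply(COVARIATE_FACTORS, function(f) nlevels(droplevels(d[[f]])) < 2, logical(1))
  terms <- COVARIATE_FACTORS[!drop_const]
  msgs <- character(0)
  if (any(drop_const))
    msgs <- c(msgs, paste("dropped constant factor(s):",
                          paste(COVARIATE_FACTORS[drop_const], collapse = ", ")))
  for (f in terms) d[[f]] <- droplevels(d[[f]])
  n_clusters <- length(unique(d$cluster_id))
  use_re <- n_clusters >= 2
  if (!use_re) {
    warning("single cluster: falling back to fixed-intercept log-binomial model")
    msgs <- c(msgs, "fixed-intercept fallback (fewer than 2 clusters)")
  }
  rhs <- paste(terms, collapse = " + ")
  converged <- FALSE; cluster_sd <- NA_real_; used_re <- FALSE
  co <- NULL; vc <- NULL
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), d)
  # log link: start the intercept at the log overall risk, slopes at zero,
  # so fitted probabilities begin strictly inside (0, 1)
  beta0 <- c(log(mean(d$.case)), rep(0, ncol(X) - 1L))
  if (use_re) {
    fml <- stats::as.formula(paste(".case ~", rhs, "+ (1 | cluster_id)"))
    fit <- tryCatch(
      suppressWarnings(  # optimizer probes of p > 1 regions; convergence is checked below
        glmmTMB::glmmTMB(fml, data = d, family = stats::binomial(link = "log"),
                         start = list(beta = beta0))),
      error = function(e) e)
    if (inherits(fit, "glmmTMB")) {
      used_re <- TRUE
      converged <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
      if (!converged) msgs <- c(msgs, "glmmTMB optimizer did not fully converge")
      cluster_sd <- tryCatch(
        sqrt(glmmTMB::VarCorr(fit)$cond$cluster_id[1, 1]),
        error = function(e) NA_real_)
      co <- glmmTMB::fixef(fit)$cond
      vc <- stats::vcov(fit)$cond
    } else {
      msgs <- c(msgs, paste("mixed-model fit failed:", conditionMessage(fit)))
    }
  }
  if (is.null(co)) {
    # fixed-intercept log-binomial fit: the <2-cluster path, and the rescue
    # path (reported, not silent) if the mixed fit errored outright
    fml <- stats::as.formula(paste(".case ~", rhs))
    fit <- tryCatch(
      stats::glm(fml, data = d, family = stats::binomial(link = "log"),
                 start = beta0),
      error = function(e) e)
    if (!inherits(fit, "glm"))
      stop("log-binomial fit failed: ", conditionMessage(fit))
    converged <- fit$converged
    if (!converged) msgs <- c(msgs, "glm IRLS did not converge")
    co <- stats::coef(fit)
    vc <- stats::vcov(fit)
    if (use_re) msgs <- c(msgs, "estimates from fixed-intercept rescue fit")
  }
  est <- rr_estimates(co, vc, d, terms)
  structure(list(estimates = est, event = event, interval = interval,
                 n_cases = sum(d$.case), n_comparison = sum(1 - d$.case),
                 n_model = nrow(d), n_clusters = n_clusters,
                 cluster_sd = cluster_sd, random_effect = used_re,
                 converged = converged, messages = msgs),
            class = "rr_result")
}

# Wald 95% CIs on the log scale, exponentiated; reference rows get rr 1, no CI
rr_estimates <- function(co, vc, d, terms) {
  rows <- list()
  z <- stats::qnorm(0.975)
  for (f in terms) {
    levs <- levels(d[[f]])
    for (i in seq_along(levs)) {
      lev <- levs[i]
      if (i == 1) {
        rows[[length(rows) + 1]] <- data.frame(
          covariate = f, level = lev, rr = 1, ci_low = NA_real_,
          ci_high = NA_real_, is_ref = TRUE, stringsAsFactors = FALSE)
      } else {
        nm <- paste0(f, lev)
        b <- co[[nm]]; se <- sqrt(vc[nm, nm])
        rows[[length(rows) + 1]] <- data.frame(
          covariate = f, level = lev, rr = exp(b),
          ci_low = exp(b - z * se), ci_high = exp(b + z * se),
          is_ref = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.rr_result <- function(x, ...) {
  iv <- if (!is.null(x$interval)) x$interval$label else "?"
  cat(sprintf("<rr_result> %s vs ongoing, %s: %d cases / %d comparisons (%d modeled), %s\n",
              x$event %||% "?", iv, x$n_cases, x$n_comparison, x$n_model,
              if (x$converged) "converged" else "NOT CONVERGED"))
  e <- x$estimates
  e$rr <- sprintf("%.2f", e$rr)
  e$ci <- ifelse(e$is_ref, "REF",
                 sprintf("(%.2f, %.2f)", e$ci_low, e$ci_high))
  print(e[c("covariate", "level", "rr", "ci")], row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit relative-risk models for every loss type and interval
#'
#' One adjusted model per event x interval combination (six for the
#' canonical intervals). Per-model failures (too few cases, separation,
#' non-convergence) are isolated: the failing cell carries the error
#' message instead of aborting the rest.
#'
#' @param records Registry data frame.
#' @param intervals List of [ga_interval()]s (default canonical three).
#' @param events Loss types to model.
#' @return Named list (`"MISCARRIAGE 6,0-7,6 weeks"`, ...) of `rr_result`
#'   objects or `try-error`-style character messages for failed cells.
#' @export
rr_table <- function(records, intervals = canonical_intervals(),
                     events = LOSS_OUTCOMES) {
  out <- list()
  for (ev in events) for (iv in intervals) {
    key <- paste(ev, iv$label)
    out[[key]] <- tryCatch({
      cs <- build_comparison_set(records, iv, ev)
      fit_rr(cs)
    }, error = function(e) structure(conditionMessage(e), class = "rr_failure"))
  }
  out
}

#' Flatten relative-risk results to a table
#'
#' @param results Output of [rr_table()] or a single `rr_result`.
#' @return Data frame with one row per event x interval x covariate level,
#'   CIs formatted as in the estimates; failed cells are skipped.
#' @export
rr_as_data_frame <- function(results) {
  if (inherits(results, "rr_result")) results <- list(results)
  rows <- list()
  for (key in names(results)) {
    r <- results[[key]]
    if (!inherits(r, "rr_result")) next
    e <- r$estimates
    e$event <- r$event %||% NA_character_
    e$interval <- if (!is.null(r$interval)) r$interval$label else NA_character_
    rows[[length(rows) + 1]] <- e
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  out[c("event", "interval", "covariate", "level", "rr", "ci_low", "ci_high", "is_ref")]
}
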