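test_that("covariate categories honor the documented cut points", {
  r <- recs(
    rec("a20", maternal_age_years = 20L), rec("a21", maternal_age_years = 21L),
    rec("a30", maternal_age_years = 30L), rec("a31", maternal_age_years = 31L))
  cc <- categorize(r)
  expect_equal(as.character(cc$age_cat), c("LE20", "A21_25", "A26_30", "GT30"))

  bmi <- categorize(rec(weight_kg = 45, height_m = 1.60))
  expect_equal(round(bmi$bmi, 1), 17.6)
  expect_equal(as.character(bmi$bmi_cat), "UNDER_18_5")
  # the 18.5-25 band is closed on both ends
  expect_equal(as.character(categorize(rec(weight_kg = 18.5, height_m = 1))$bmi_cat),
               "NORMAL_18_5_25")
  expect_equal(as.character(categorize(rec(weight_kg = 25, height_m = 1))$bmi_cat),
               "NORMAL_18_5_25")
  expect_equal(as.character(categorize(rec(weight_kg = 25.01, height_m = 1))$bmi_cat),
               "OVER_25")

  hb <- categorize(recs(rec(hemoglobin_g_dl = 9.0), rec(hemoglobin_g_dl = 9.1),
                        rec(hemoglobin_g_dl = 11.0), rec(hemoglobin_g_dl = 11.1)))
  expect_equal(as.character(hb$hb_cat),
               c("SEV_MOD_LE9", "MILD_9_11", "MILD_9_11", "NORMAL_GT11"))

  par <- categorize(recs(rec(parity = 0L), rec(parity = 2L), rec(parity = 3L)))
  expect_equal(as.character(par$parity_cat), c("P0", "P1_2", "GT2"))

  # reference levels come first so model contrasts are against them
  expect_equal(levels(cc$age_cat)[1], "A21_25")
  expect_equal(levels(cc$education_cat)[1], "PRIMARY")
  expect_error(categorize(rec(weight_kg = -1)), "non-positive")
})

test_that("cases, comparisons, competing losses and late enrollees partition the risk set", {
  g <- generate_registry(registry_config(n_women = 6000), seed = 31)
  kept <- exclude_unknown_ga(g$records)$records
  iv <- canonical_intervals()$ga_8_12
  cs <- build_comparison_set(kept, iv, "MISCARRIAGE")
  rs <- build_risk_set(kept, iv)
  competing <- count_interval_events(kept, iv, "MTP")
  expect_equal(nrow(cs$cases) + nrow(cs$comparisons) + competing, rs$n)
  expect_equal(nrow(cs$cases), count_interval_events(kept, iv, "MISCARRIAGE"))
  # comparisons were all still ongoing at the interval end
  lost <- cs$comparisons$outcome %in% c("MISCARRIAGE", "MTP") &
    cs$comparisons$outcome_ga_days < iv$end_days
  expect_false(any(lost, na.rm = TRUE))
})

test_that("fitting is refused without at least two cases and two comparisons", {
  r <- block_registry(50, 0, 0, loss_day = 60)
  iv <- ga_interval(56, 84)
  cs <- build_comparison_set(r, iv, "MISCARRIAGE")
  expect_error(fit_rr(cs), "refused")
})

test_that("without a random effect the 2x2 fit equals the closed-form risk ratio", {
  # single cluster forces the fixed-intercept fallback (with a warning);
  # collapse covariates to one binary factor by making all others constant
  a <- 30L; b <- 170L; c_ <- 20L; d_ <- 380L  # exposed/unexposed cases/non-cases
  exposed <- rep(c(TRUE, FALSE), c(a + b, c_ + d_))
  case <- c(rep(c(1L, 0L), c(a, b)), rep(c(1L, 0L), c(c_, d_)))
  n <- length(case)
  r <- block_registry(n, 0, 0, loss_day = 60)
  r$outcome <- ifelse(case == 1L, "MISCARRIAGE", "LIVEBIRTH")
  r$outcome_ga_days <- ifelse(case == 1L, 60L, 280L)
  r$neonatal_death_by_28d <- ifelse(case == 1L, NA, FALSE)
  r$maternal_age_years <- ifelse(exposed, 35L, 23L)   # GT30 vs reference
  iv <- ga_interval(56, 84)
  cs <- build_comparison_set(r, iv, "MISCARRIAGE")
  fit <- suppressWarnings(fit_rr(cs))
  expect_false(fit$random_effect)
  got <- fit$estimates[fit$estimates$level == "GT30", ]

  rr <- (a / (a + b)) / (c_ / (c_ + d_))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c_ - 1 / (c_ + d_))
  expect_equal(got$rr, rr, tolerance = 1e-6)
  expect_equal(got$ci_low, rr * exp(-qnorm(0.975) * se), tolerance = 1e-4)
  expect_equal(got$ci_high, rr * exp(qnorm(0.975) * se), tolerance = 1e-4)
})

test_that("a planted covariate effect is recovered by the mixed model", {
  cfg <- registry_config(
    n_women = 8000, n_clusters = 12,
    covariate_rr = list(MISCARRIAGE = numeric(0),
                        MTP = c("age_cat:GT30" = 2.19)))
  g <- generate_registry(cfg, seed = 41)
  kept <- exclude_unknown_ga(g$records)$records
  iv <- canonical_intervals()$ga_12_20
  fit <- fit_rr(build_comparison_set(kept, iv, "MTP"))
  expect_true(fit$converged)
  expect_true(fit$random_effect)
  got <- fit$estimates[fit$estimates$level == "GT30", ]
  # crude single-replicate check: inside the fit's own 95% CI
  expect_gt(got$ci_high, 2.19 * 0.8)
  expect_lt(got$ci_low, 2.19 * 1.2)
  expect_true(all(fit$estimates$rr[fit$estimates$is_ref] == 1))
  expect_true(all(is.na(fit$estimates$ci_low[fit$estimates$is_ref])))
})

test_that("estimates are invariant to cluster relabeling and record order", {
  g <- generate_registry(registry_config(n_women = 4000, n_clusters = 8), seed = 51)
  kept <- exclude_unknown_ga(g$records)$records
  iv <- canonical_intervals()$ga_12_20
  base <- fit_rr(build_comparison_set(kept, iv, "MISCARRIAGE"))
  perm <- kept[sample(nrow(kept)), ]
  relab <- setNames(sprintf("K%02d", sample(8)), unique(perm$cluster_id))
  perm$cluster_id <- unname(relab[perm$cluster_id])
  alt <- fit_rr(build_comparison_set(perm, iv, "MISCARRIAGE"))
  expect_equal(alt$estimates$rr, base$estimates$rr, tolerance = 1e-4)
})

test_that("the full table isolates per-cell failures and keeps the layout", {
  g <- generate_registry(registry_config(n_women = 4000, n_clusters = 6), seed = 61)
  kept <- exclude_unknown_ga(g$records)$records
  res <- rr_table(kept)
  expect_length(res, 6)
  ok <- vapply(res, inherits, logical(1), "rr_result")
  expect_true(all(ok))
  tab <- rr_as_data_frame(res)
  expect_setequal(unique(tab$covariate),
                  c("age_cat", "education_cat", "parity_cat", "bmi_cat", "hb_cat"))
  expect_true(all(tab$rr[tab$is_ref] == 1))
  # a registry with no MTPs at all fails those cells but not the rest
  no_mtp <- kept[kept$outcome != "MTP" | is.na(kept$outcome), ]
  res2 <- rr_table(no_mtp)
  classes <- vapply(res2, inherits, logical(1), "rr_result")
  expect_true(any(classes))
  expect_true(any(!classes))
})
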