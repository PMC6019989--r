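test_that("risk-set membership follows enrollment and prior-loss rules", {
  w <- rec("W1", enroll_ga_days = 40L, outcome = "MISCARRIAGE",
           outcome_ga_days = 90L, neonatal_death_by_28d = NA)
  rs_mid <- build_risk_set(w, ga_interval(56, 84))
  expect_equal(rs_mid$n, 1)          # enrolled before 56, loss at 90 >= 56
  rs_in <- build_risk_set(w, ga_interval(84, 140))
  expect_equal(rs_in$n, 1)           # the loss at 90 falls inside this interval
  expect_equal(count_interval_events(w, ga_interval(84, 140), "MISCARRIAGE"), 1)
  rs_late <- build_risk_set(w, ga_interval(98, 140))
  expect_equal(rs_late$n, 0)         # loss at 90 < 98 removes her

  # enrolling mid-interval defers membership to the next interval
  mid <- rec("W2", enroll_ga_days = 60L)
  expect_equal(build_risk_set(mid, ga_interval(56, 84))$n, 0)
  expect_equal(build_risk_set(mid, ga_interval(84, 140))$n, 1)

  # ongoing pregnancies (no outcome) count; stillbirths never remove early
  ongoing <- rec("W3", outcome = NA, outcome_ga_days = NA,
                 neonatal_death_by_28d = NA)
  sb <- rec("W4", outcome = "STILLBIRTH", outcome_ga_days = 150L,
            neonatal_death_by_28d = NA)
  expect_equal(build_risk_set(recs(ongoing, sb), ga_interval(84, 140))$n, 2)
})

test_that("event counting respects the half-open day boundary", {
  r <- recs(
    rec("W1", outcome = "MISCARRIAGE", outcome_ga_days = 84L,
        neonatal_death_by_28d = NA),
    rec("W2", outcome = "MISCARRIAGE", outcome_ga_days = 83L,
        neonatal_death_by_28d = NA))
  expect_equal(count_interval_events(r, ga_interval(56, 84), "MISCARRIAGE"), 1)
  expect_equal(count_interval_events(r, ga_interval(84, 140), "MISCARRIAGE"), 1)
  expect_equal(count_interval_events(r, ga_interval(42, 56), "MISCARRIAGE"), 0)
})

test_that("rates follow the competing-event denominator-exclusion convention", {
  r <- block_registry(2775, 307, 112, loss_day = 50)
  iv <- ga_interval(42, 56)
  misc <- interval_rate(r, iv, "MISCARRIAGE")
  expect_equal(misc$numerator, 307)
  expect_equal(misc$denominator, 2775 - 112)
  expect_equal(round(misc$rate_per_1000, 1), 115.3)
  mtp <- interval_rate(r, iv, "MTP")
  expect_equal(mtp$denominator, 2775 - 307)
  expect_equal(round(mtp$rate_per_1000, 1), 45.4)

  # with no competing events the denominator is the whole risk set
  solo <- block_registry(100, 10, 0, loss_day = 50)
  expect_equal(interval_rate(solo, iv, "MISCARRIAGE")$denominator, 100)

  # an empty denominator is an explicit error, not NaN
  expect_error(interval_rate(rec(enroll_ga_days = 100L), iv, "MISCARRIAGE"),
               "zero denominator")
})

test_that("counts planted by the generator are recovered exactly", {
  g <- generate_registry(registry_config(n_women = 5000), seed = 21)
  kept <- exclude_unknown_ga(g$records)$records
  truth <- g$truth$women[!g$truth$women$ga_missing, ]
  for (iv in canonical_intervals()) for (ev in c("MISCARRIAGE", "MTP")) {
    planted <- sum(truth$event == ev & !is.na(truth$loss_interval) &
                     truth$loss_interval == iv$label)
    expect_equal(count_interval_events(kept, iv, ev), planted)
  }
})

test_that("interval rates equal the brute-force per-woman oracle", {
  for (seed in c(101, 202, 303)) {
    r <- random_raw_registry(n = sample(50:200, 1), seed = seed)
    for (iv in canonical_intervals()) {
      o <- oracle_interval_stats(r, iv$start_days, iv$end_days)
      rs <- build_risk_set(r, iv)
      expect_equal(rs$n, o$n_risk)
      expect_equal(count_interval_events(r, iv, "MISCARRIAGE"), o$n_misc)
      expect_equal(count_interval_events(r, iv, "MTP"), o$n_mtp)
      if (o$den_misc > 0) {
        got <- interval_rate(r, iv, "MISCARRIAGE")
        expect_equal(got$denominator, o$den_misc)
        expect_equal(got$rate_per_1000, 1000 * o$n_misc / o$den_misc)
      }
    }
  }
})

test_that("denominator identity and risk-set monotonicity hold on generated data", {
  g <- generate_registry(registry_config(n_women = 8000), seed = 5)
  kept <- exclude_unknown_ga(g$records)$records
  ivs <- canonical_intervals()
  prev_members <- NULL
  for (iv in ivs) {
    rs <- build_risk_set(kept, iv)
    n_m <- count_interval_events(kept, iv, "MISCARRIAGE")
    n_t <- count_interval_events(kept, iv, "MTP")
    expect_equal(interval_rate(kept, iv, "MISCARRIAGE")$denominator + n_t, rs$n)
    expect_equal(interval_rate(kept, iv, "MTP")$denominator + n_m, rs$n)
    if (!is.null(prev_members)) {
      # members of this interval who had already enrolled before the previous
      # start must be a subset of the previous risk set (losses only shrink it)
      early <- rs$members$woman_id[rs$members$enroll_ga_days < iv_prev$start_days]
      expect_true(all(early %in% prev_members))
    }
    prev_members <- rs$member_ids
    iv_prev <- iv
  }
})

test_that("rates are invariant to record order and id relabeling", {
  r <- random_raw_registry(150, seed = 7)
  iv <- ga_interval(56, 84)
  base <- interval_rate(r, iv, "MISCARRIAGE")
  shuffled <- r[sample(nrow(r)), ]
  relabeled <- shuffled
  relabeled$woman_id <- sprintf("Z%04d", seq_len(nrow(relabeled)))
  expect_equal(interval_rate(shuffled, iv, "MISCARRIAGE"), base)
  expect_equal(interval_rate(relabeled, iv, "MISCARRIAGE"), base)
})

test_that("the rate table covers both events across the canonical intervals", {
  g <- generate_registry(registry_config(n_women = 5000), seed = 9)
  kept <- exclude_unknown_ga(g$records)$records
  rt <- rate_table(kept)
  expect_equal(nrow(rt), 6)
  expect_setequal(unique(rt$event), c("MISCARRIAGE", "MTP"))
  expect_equal(rt$rate_per_1000, 1000 * rt$n_event / rt$n_at_risk)
  expect_error(rate_table(rec()[0, ]), "zero denominator")
})
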