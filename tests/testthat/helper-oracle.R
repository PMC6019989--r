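# Independent brute-force oracle for interval rates: a plain per-woman scan
# with scalar logic, no vectorization shared with the package code.

oracle_interval_stats <- function(records, start_days, end_days) {
  n_risk <- 0L; n_misc <- 0L; n_mtp <- 0L
  for (i in seq_len(nrow(records))) {
    enroll <- records$enroll_ga_days[i]
    if (is.na(enroll) || enroll >= start_days) next
    out <- records$outcome[i]
    oga <- records$outcome_ga_days[i]
    is_loss <- !is.na(out) && (out == "MISCARRIAGE" || out == "MTP")
    if (is_loss && !is.na(oga) && oga < start_days) next  # lost before interval
    n_risk <- n_risk + 1L
    if (is_loss && !is.na(oga) && oga >= start_days && oga < end_days) {
      if (out == "MISCARRIAGE") n_misc <- n_misc + 1L else n_mtp <- n_mtp + 1L
    }
  }
  list(n_risk = n_risk, n_misc = n_misc, n_mtp = n_mtp,
       den_misc = n_risk - n_mtp, den_mtp = n_risk - n_misc)
}
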