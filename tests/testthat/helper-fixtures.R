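# Small hand-built registries for unit tests.

# one row per call site; defaults give a valid live birth at term
rec <- function(woman_id = "W1", cluster_id = "C1", enroll_ga_days = 30L,
                outcome = "LIVEBIRTH", outcome_ga_days = 280L,
                neonatal_death_by_28d = if (identical(outcome, "LIVEBIRTH")) FALSE else NA,
                maternal_age_years = 24L, education = "PRIMARY", parity = 1L,
                weight_kg = 50, height_m = 1.55, hemoglobin_g_dl = 11.5,
                anc_visits = 2L, attendant = "PHYSICIAN", location = "HOSPITAL") {
  data.frame(woman_id = woman_id, cluster_id = cluster_id,
             enroll_ga_days = enroll_ga_days, outcome = outcome,
             outcome_ga_days = outcome_ga_days,
             neonatal_death_by_28d = neonatal_death_by_28d,
             maternal_age_years = maternal_age_years, education = education,
             parity = parity, weight_kg = weight_kg, height_m = height_m,
             hemoglobin_g_dl = hemoglobin_g_dl, anc_visits = anc_visits,
             attendant = attendant, location = location,
             stringsAsFactors = FALSE)
}

recs <- function(...) do.call(rbind, list(...))

# a registry whose first-interval arithmetic reproduces a known risk set:
# `n_risk` women enrolled on day 30, of whom `n_misc` miscarry and `n_mtp`
# terminate on `loss_day`, the rest delivering at term
block_registry <- function(n_risk, n_misc, n_mtp, loss_day, id_prefix = "B") {
  stopifnot(n_misc + n_mtp <= n_risk)
  outcome <- rep("LIVEBIRTH", n_risk)
  outcome[seq_len(n_misc)] <- "MISCARRIAGE"
  if (n_mtp > 0) outcome[n_misc + seq_len(n_mtp)] <- "MTP"
  data.frame(
    woman_id = sprintf("%s%06d", id_prefix, seq_len(n_risk)),
    cluster_id = "C1", enroll_ga_days = 30L, outcome = outcome,
    outcome_ga_days = ifelse(outcome == "LIVEBIRTH", 280L, as.integer(loss_day)),
    neonatal_death_by_28d = ifelse(outcome == "LIVEBIRTH", FALSE, NA),
    maternal_age_years = 24L, education = "PRIMARY", parity = 1L,
    weight_kg = 50, height_m = 1.55, hemoglobin_g_dl = 11.5, anc_visits = 2L,
    attendant = "PHYSICIAN", location = "HOSPITAL", stringsAsFactors = FALSE)
}

# a deliberately messy random registry: staggered enrollment, all four
# outcomes, some still-ongoing pregnancies (NA outcome), some missing fields
random_raw_registry <- function(n, seed) {
  set.seed(seed)
  enroll <- sample(0:150, n, replace = TRUE)
  outcome <- sample(c("MISCARRIAGE", "MTP", "STILLBIRTH", "LIVEBIRTH", NA),
                    n, replace = TRUE, prob = c(0.2, 0.15, 0.05, 0.45, 0.15))
  oga <- ifelse(is.na(outcome), NA_integer_,
         ifelse(outcome %in% c("MISCARRIAGE", "MTP"),
                enroll + sample(1:100, n, TRUE),
                pmax(enroll + 1L, sample(140:300, n, TRUE))))
  oga <- pmin(oga, ifelse(!is.na(outcome) & outcome == "MISCARRIAGE", 139L, 310L))
  data.frame(
    woman_id = sprintf("R%05d", seq_len(n)),
    cluster_id = sprintf("C%d", sample(1:5, n, TRUE)),
    enroll_ga_days = enroll, outcome = outcome, outcome_ga_days = oga,
    neonatal_death_by_28d = ifelse(!is.na(outcome) & outcome == "LIVEBIRTH",
                                   FALSE, NA),
    maternal_age_years = sample(16:40, n, TRUE),
    education = sample(c("NONE", "PRIMARY", "SECONDARY", "UNIVERSITY_PLUS"), n, TRUE),
    parity = sample(0:4, n, TRUE),
    weight_kg = round(runif(n, 38, 75), 1), height_m = round(runif(n, 1.4, 1.8), 2),
    hemoglobin_g_dl = round(runif(n, 6, 14), 1),
    anc_visits = sample(0:6, n, TRUE),
    attendant = sample(c("PHYSICIAN", "NURSE_MIDWIFE", "TBA", "FAMILY_SELF_OTHER"), n, TRUE),
    location = sample(c("HOSPITAL", "CLINIC_HEALTH_CENTER", "HOME_OTHER"), n, TRUE),
    stringsAsFactors = FALSE)
}
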