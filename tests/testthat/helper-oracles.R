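# Independent oracles: deliberately re-derived, per-record, decision-table
# implementations of the involvement / scoring rules, kept separate from the
# package's vectorized code paths so agreement is a real check.

oracle_hepatic_list <- c(
  "hepatomegaly", "splenomegaly", "varices", "ascites", "elevated_alt",
  "elevated_ggt", "elevated_alp", "prolonged_pt_inr", "hyperbilirubinemia",
  "low_albumin", "fasting_hypoglycemia", "liver_failure",
  "hepatic_synthetic_dysfunction", "jaundice", "gi_bleed")
oracle_nm_list <- c(
  "contractures", "ventilator_dependent_respiratory_weakness", "hypotonia",
  "hyporeflexia", "atrophy_or_hypotrophy", "abnormal_motor_development",
  "abnormal_emg_or_ncv", "weakness_or_exercise_intolerance")
oracle_cardiac_list <- c(
  "cardiomyopathy", "systolic_dysfunction", "cardiac_hypertrophy",
  "cardiomegaly", "conduction_defect")

# One record = one row of a cohort tibble (with findings list-column).
oracle_assess <- function(rec, system) {
  fnd <- rec$findings[[1]]
  hits <- 0
  if (nrow(fnd) > 0) {
    for (i in seq_len(nrow(fnd))) {
      code <- fnd$code[i]
      if (system == "hepatic" && code %in% oracle_hepatic_list) {
        dropped <- FALSE
        if (code %in% c("fasting_hypoglycemia", "hyperbilirubinemia") &&
            isTRUE(fnd$newborn_period_only[i])) dropped <- TRUE
        if (code == "ascites" && isTRUE(fnd$heart_failure_context_only[i])) {
          dropped <- TRUE
        }
        if (!dropped) hits <- hits + 1
      }
      if (system == "neuromuscular" && code %in% oracle_nm_list) hits <- hits + 1
      if (system == "cardiac" && code %in% oracle_cardiac_list) hits <- hits + 1
    }
  }
  if (hits > 0) return("present")
  flag <- rec[[paste0("explicit_normal_", system)]]
  if (isTRUE(flag)) "absent" else "unknown"
}

oracle_severe <- function(rec) {
  fnd <- rec$findings[[1]]
  if (nrow(fnd) == 0) return(FALSE)
  for (i in seq_len(nrow(fnd))) {
    code <- fnd$code[i]
    if (code %in% c("liver_failure", "hepatic_synthetic_dysfunction",
                    "jaundice", "varices", "gi_bleed")) return(TRUE)
    if (code == "hyperbilirubinemia" && !isTRUE(fnd$newborn_period_only[i])) {
      return(TRUE)
    }
    if (code == "ascites" && !isTRUE(fnd$heart_failure_context_only[i])) {
      return(TRUE)
    }
    if (code == "splenomegaly" && !is.na(fnd$platelet_count[i]) &&
        fnd$platelet_count[i] < 150000) return(TRUE)
  }
  FALSE
}

oracle_n_score <- function(rec) {
  inv <- oracle_assess(rec, "neuromuscular")
  if (inv == "absent") return("N0")
  if (inv == "unknown") return("unscorable")
  onset <- rec$neuromuscular_onset
  if (onset == "postnatal") return("N1")
  if (!onset %in% c("prenatal", "at_birth")) return("unscorable")
  dage <- rec$age_at_death_months
  if (rec$vital_status == "deceased" && !is.na(dage)) {
    return(if (dage < 6) "N3" else "N2")
  }
  fu <- rec$age_at_last_followup_months
  tx <- rec$age_at_transplant_months
  if ((!is.na(fu) && fu >= 6) || (!is.na(tx) && tx >= 6)) return("N2")
  "unscorable"
}

oracle_h_score <- function(rec) {
  inv <- oracle_assess(rec, "hepatic")
  if (inv == "absent") return("H0")
  if (inv == "unknown") return("unscorable")
  if (!oracle_severe(rec)) return("H1")
  tx <- rec$age_at_transplant_months
  if (rec$liver_transplant == "yes" && !is.na(tx) && tx < 60) return("H3")
  dage <- rec$age_at_death_months
  if (rec$vital_status == "deceased" && !is.na(dage) && dage < 60) return("H3")
  fu <- rec$age_at_last_followup_months
  if ((!is.na(dage) && dage >= 60) || (!is.na(fu) && fu >= 60) ||
      (!is.na(tx) && tx >= 60)) return("H2")
  "unscorable"
}

oracle_venn <- function(h, n, c) {
  statuses <- c(h, n, c)
  if (any(statuses == "unknown")) return("not_assessable")
  present <- statuses == "present"
  k <- sum(present)
  if (k == 0) return("none_involved")
  if (k == 3) return("all_three")
  if (k == 1) {
    return(c("hepatic_only", "neuromuscular_only", "cardiac_only")[present])
  }
  if (present[1] && present[2]) return("hepatic_neuromuscular")
  if (present[1] && present[3]) return("hepatic_cardiac")
  "neuromuscular_cardiac"
}

oracle_subtype <- function(n, h) {
  if (n == "unscorable" || h == "unscorable") return("unclassifiable")
  key <- paste(n, h, sep = "-")
  table <- c(
    "N0-H0" = "no_hepatic_no_neuromuscular",
    "N0-H1" = "non_progressive_hepatic",
    "N0-H2" = "intermediate_hepatic",
    "N0-H3" = "classic_hepatic",
    "N1-H0" = "juvenile_neuromuscular",
    "N2-H0" = "intermediate_neuromuscular",
    "N3-H0" = "perinatal_congenital_neuromuscular")
  if (key %in% names(table)) unname(table[key]) else "mixed"
}

# Randomized (valid, non-prenatal) record generator for property tests.
# Uses its own code lists and respects the record invariants by construction.
random_record <- function(id) {
  all_codes <- c(oracle_hepatic_list, oracle_nm_list, oracle_cardiac_list,
                 "other_neurological", "structural_cardiac_defect")
  n_f <- sample(0:4, 1)
  codes <- sample(all_codes, n_f, replace = TRUE)
  fnd <- gsdiv::findings(codes)
  if (n_f > 0) {
    fnd$newborn_period_only <-
      fnd$code %in% c("fasting_hypoglycemia", "hyperbilirubinemia") &
      runif(n_f) < 0.4
    fnd$heart_failure_context_only <- fnd$code == "ascites" & runif(n_f) < 0.4
    fnd$platelet_count <- ifelse(fnd$code == "splenomegaly" & runif(n_f) < 0.7,
                                 runif(n_f, 50000, 400000), NA_real_)
  }
  has_sys <- function(lst) any(codes %in% lst)
  vital <- sample(c("alive", "deceased", "unknown"), 1,
                  prob = c(0.45, 0.4, 0.15))
  transplant <- sample(c("yes", "no", "unknown"), 1, prob = c(0.2, 0.4, 0.4))
  gsdiv::patient_record(
    id, fnd,
    neuromuscular_onset = sample(c("prenatal", "at_birth", "postnatal",
                                   "none_reported", "unknown"), 1),
    vital_status = vital,
    age_at_death_months = if (vital == "deceased" && runif(1) < 0.8) {
      runif(1, 0, 260)
    } else NA_real_,
    age_at_last_followup_months = if (runif(1) < 0.7) runif(1, 0, 260)
                                  else NA_real_,
    liver_transplant = transplant,
    age_at_transplant_months = if (transplant == "yes") runif(1, 1, 200)
                               else NA_real_,
    explicit_normal_hepatic = !has_sys(oracle_hepatic_list) & runif(1) < 0.5,
    explicit_normal_neuromuscular = !has_sys(oracle_nm_list) & runif(1) < 0.5,
    explicit_normal_cardiac = !has_sys(oracle_cardiac_list) & runif(1) < 0.5,
    death_attributed_hepatic = sample(c(TRUE, FALSE, NA), 1)
  )
}

random_cohort <- function(n, prefix = "R") {
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    random_record(sprintf("%s%04d", prefix, i))
  }))
}
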