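# Registry of coded clinical findings and the organ system each belongs to.
# "non_qualifying" codes are stored for provenance but never contribute to
# involvement assessment or severity scoring (neurological abnormalities not
# attributable to GSD IV; structural cardiac defects other than cardiomyopathy).

.hepatic_codes <- c(
  "hepatomegaly", "splenomegaly", "varices", "ascites",
  "elevated_alt", "elevated_ggt", "elevated_alp", "prolonged_pt_inr",
  "hyperbilirubinemia", "low_albumin", "fasting_hypoglycemia",
  "liver_failure", "hepatic_synthetic_dysfunction", "jaundice", "gi_bleed"
)

.neuromuscular_codes <- c(
  "contractures", "ventilator_dependent_respiratory_weakness", "hypotonia",
  "hyporeflexia", "atrophy_or_hypotrophy", "abnormal_motor_development",
  "abnormal_emg_or_ncv", "weakness_or_exercise_intolerance"
)

.cardiac_codes <- c(
  "cardiomyopathy", "systolic_dysfunction", "cardiac_hypertrophy",
  "cardiomegaly", "conduction_defect"
)

.non_qualifying_codes <- c("other_neurological", "structural_cardiac_defect")

# Severe hepatic features: liver failure or synthetic dysfunction; jaundice or
# hyperbilirubinemia; ascites; varices or GI bleed; splenomegaly is severe only
# together with documented thrombocytopenia (platelets < 150,000/µl), handled
# separately in has_severe_hepatic_features().
.severe_hepatic_codes <- c(
  "liver_failure", "hepatic_synthetic_dysfunction", "jaundice",
  "hyperbilirubinemia", "ascites", "varices", "gi_bleed"
)

.platelet_threshold <- 150000

#' Coded clinical findings recognized by the package
#'
#' Returns the registry of clinical finding codes, the organ system group each
#' belongs to (hepatic, neuromuscular, cardiac, or non_qualifying), and whether
#' the code can count as a severe hepatic feature. Non-qualifying codes (e.g.
#' childhood epilepsy recorded as `other_neurological`, a ventricular septal
#' defect recorded as `structural_cardiac_defect`) are retained in records for
#' provenance but are ignored by involvement assessment and scoring.
#'
#' @return A tibble with columns `code`, `system`, and `severe_hepatic`.
#' @examples
#' finding_codes()
#' @export
finding_codes <- function() {
  tibble(
    code = c(.hepatic_codes, .neuromuscular_codes, .cardiac_codes,
             .non_qualifying_codes),
    system = c(
      rep("hepatic", length(.hepatic_codes)),
      rep("neuromuscular", length(.neuromuscular_codes)),
      rep("cardiac", length(.cardiac_codes)),
      rep("non_qualifying", length(.non_qualifying_codes))
    )
  ) %>%
    mutate(severe_hepatic = .data$code %in% c(.severe_hepatic_codes,
                                              "splenomegaly"))
}

.all_codes <- function() {
  c(.hepatic_codes, .neuromuscular_codes, .cardiac_codes, .non_qualifying_codes)
}

# Zero-row findings tibble with the canonical column set.
empty_findings <- function() {
  tibble(
    code = character(),
    newborn_period_only = logical(),
    heart_failure_context_only = logical(),
    platelet_count = double(),
    age_first_observed_months = double()
  )
}

#' Build a findings table for one patient
#'
#' Convenience constructor for the `findings` list-column of a cohort. Each
#' finding is a coded observation with optional qualifiers: whether
#' hypoglycemia/hyperbilirubinemia was limited to the immediate newborn period,
#' whether ascites occurred exclusively in the setting of heart failure, a
#' platelet count (per µl, qualifying splenomegaly as portal-hypertensive), and
#' the age at first observation in months.
#'
#' @param code Character vector of finding codes (see [finding_codes()]).
#' @param newborn_period_only Logical, recycled; only meaningful for
#'   `fasting_hypoglycemia` and `hyperbilirubinemia`.
#' @param heart_failure_context_only Logical, recycled; only meaningful for
#'   `ascites`.
#' @param platelet_count Numeric platelet count per µl, or `NA`.
#' @param age_first_observed_months Numeric age in months, or `NA`.
#' @return A tibble of findings, one row per code.
#' @examples
#' findings("hepatomegaly")
#' findings(c("splenomegaly", "hypotonia"), platelet_count = c(120000, NA))
#' @export
findings <- function(code = character(),
                     newborn_period_only = FALSE,
                     heart_failure_context_only = FALSE,
                     platelet_count = NA_real_,
                     age_first_observed_months = NA_real_) {
  if (length(code) == 0) return(empty_findings())
  tibble(
    code = as.character(code),
    newborn_period_only = vctrs::vec_recycle(as.logical(newborn_period_only),
                                             length(code)),
    heart_failure_context_only = vctrs::vec_recycle(
      as.logical(heart_failure_context_only), length(code)),
    platelet_count = vctrs::vec_recycle(as.double(platelet_count), length(code)),
    age_first_observed_months = vctrs::vec_recycle(
      as.double(age_first_observed_months), length(code))
  )
}

# Qualifying findings for one system after the exclusion qualifiers are
# applied. Exclusions remove a finding from consideration entirely: hepatic
# hypoglycemia/hyperbilirubinemia limited to the newborn period, and ascites
# occurring only in heart failure, were not used for hepatic characterization.
qualifying_findings <- function(fnd, system) {
  if (is.null(fnd) || nrow(fnd) == 0) return(empty_findings())
  codes <- switch(system,
    hepatic = .hepatic_codes,
    neuromuscular = .neuromuscular_codes,
    cardiac = .cardiac_codes,
    abort(sprintf("unknown system '%s'", system))
  )
  keep <- fnd$code %in% codes
  if (system == "hepatic") {
    excluded <-
      (fnd$code %in% c("fasting_hypoglycemia", "hyperbilirubinemia") &
         fnd$newborn_period_only %in% TRUE) |
      (fnd$code == "ascites" & fnd$heart_failure_context_only %in% TRUE)
    keep <- keep & !excluded
  }
  fnd[keep, , drop = FALSE]
}
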