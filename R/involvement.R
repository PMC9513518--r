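.venn_levels <- c("hepatic_only", "neuromuscular_only", "cardiac_only",
                  "hepatic_neuromuscular", "hepatic_cardiac",
                  "neuromuscular_cardiac", "all_three", "none_involved",
                  "not_assessable")

.check_not_prenatal <- function(cohort, what) {
  if (any(cohort$prenatal_death %in% TRUE)) {
    abort(sprintf(
      "%s is undefined for prenatal deaths; drop them first (see drop_prenatal)",
      what))
  }
}

assess_system <- function(cohort, system) {
  flag <- cohort[[paste0("explicit_normal_", system)]]
  n_qual <- map_dbl(cohort$findings, ~nrow(qualifying_findings(.x, system)))
  case_when(
    n_qual > 0 ~ "present",
    flag ~ "absent",
    TRUE ~ "unknown"
  )
}

#' Assess hepatic involvement
#'
#' Hepatic involvement is present given any current or prior qualifying
#' hepatic finding (hepatomegaly, splenomegaly, varices, ascites, or
#' laboratory abnormalities). Hypoglycemia or hyperbilirubinemia limited to
#' the immediate newborn period and ascites occurring exclusively in heart
#' failure are excluded from consideration entirely. Involvement is absent
#' only when no qualifying finding survives the exclusions *and* the source
#' explicitly stated the liver was normal; otherwise it is unknown.
#'
#' @param cohort A cohort tibble with no prenatal-death rows.
#' @return Character vector (`"present"`, `"absent"`, `"unknown"`), one
#'   element per patient.
#' @export
assess_hepatic <- function(cohort) {
  cohort <- as_cohort(cohort)
  .check_not_prenatal(cohort, "involvement assessment")
  assess_system(cohort, "hepatic")
}

#' Assess neuromuscular involvement
#'
#' Present given any qualifying neuromuscular finding (contractures,
#' ventilator-dependent respiratory weakness, hypotonia, hyporeflexia,
#' atrophy/hypotrophy, abnormal motor development, abnormal EMG/NCV, or
#' weakness/exercise intolerance). Neurological abnormalities not attributable
#' to GSD IV (`other_neurological`) are ignored. Absent only with an explicit
#' statement that development and/or the neuromuscular examination were
#' normal.
#'
#' @inheritParams assess_hepatic
#' @return Character vector of statuses.
#' @export
assess_neuromuscular <- function(cohort) {
  cohort <- as_cohort(cohort)
  .check_not_prenatal(cohort, "involvement assessment")
  assess_system(cohort, "neuromuscular")
}

#' Assess cardiac involvement
#'
#' Present given any qualifying cardiac finding (cardiomyopathy, systolic
#' dysfunction, cardiac hypertrophy, cardiomegaly, or conduction defects).
#' Structural cardiac defects other than cardiomyopathy
#' (`structural_cardiac_defect`) are ignored. Absent only with an explicit
#' normal cardiac evaluation.
#'
#' @inheritParams assess_hepatic
#' @return Character vector of statuses.
#' @export
assess_cardiac <- function(cohort) {
  cohort <- as_cohort(cohort)
  .check_not_prenatal(cohort, "involvement assessment")
  assess_system(cohort, "cardiac")
}

#' Map tri-system statuses to Venn categories
#'
#' Deterministic mapping of the per-system present/absent pattern onto the
#' eight Venn regions; any unknown status yields `not_assessable`.
#'
#' @param hepatic,neuromuscular,cardiac Character vectors of involvement
#'   statuses (`"present"`, `"absent"`, `"unknown"`), recycled to a common
#'   length.
#' @return Character vector of Venn categories.
#' @examples
#' venn_category("present", "present", "absent")
#' @export
venn_category <- function(hepatic, neuromuscular, cardiac) {
  n <- max(length(hepatic), length(neuromuscular), length(cardiac))
  h <- vctrs::vec_recycle(hepatic, n)
  nm <- vctrs::vec_recycle(neuromuscular, n)
  cd <- vctrs::vec_recycle(cardiac, n)
  ok <- c("present", "absent", "unknown")
  if (!all(c(h, nm, cd) %in% ok)) {
    abort("involvement statuses must be 'present', 'absent' or 'unknown'")
  }
  hp <- h == "present"; np <- nm == "present"; cp <- cd == "present"
  case_when(
    h == "unknown" | nm == "unknown" | cd == "unknown" ~ "not_assessable",
    hp & np & cp ~ "all_three",
    hp & np ~ "hepatic_neuromuscular",
    hp & cp ~ "hepatic_cardiac",
    np & cp ~ "neuromuscular_cardiac",
    hp ~ "hepatic_only",
    np ~ "neuromuscular_only",
    cp ~ "cardiac_only",
    TRUE ~ "none_involved"
  )
}

#' Assess involvement of all three systems
#'
#' Runs the hepatic, neuromuscular, and cardiac involvement criteria over a
#' cohort and assigns each patient a Venn category. Patients who died in
#' utero are never assessed; by default they are dropped from the result.
#'
#' @param cohort A cohort tibble.
#' @param drop_prenatal Drop prenatal-death rows (default `TRUE`). With
#'   `FALSE`, any prenatal-death row raises an error.
#' @return A tibble with columns `patient_id`, `hepatic`, `neuromuscular`,
#'   `cardiac`, `venn`.
#' @examples
#' coh <- patient_record("L1", findings(c("hepatomegaly", "hypotonia")),
#'                       explicit_normal_cardiac = TRUE)
#' assess_involvement(coh)
#' @export
assess_involvement <- function(cohort, drop_prenatal = TRUE) {
  cohort <- as_cohort(cohort)
  if (drop_prenatal) cohort <- filter(cohort, !.data$prenatal_death)
  .check_not_prenatal(cohort, "involvement assessment")
  tibble(
    patient_id = cohort$patient_id,
    hepatic = assess_system(cohort, "hepatic"),
    neuromuscular = assess_system(cohort, "neuromuscular"),
    cardiac = assess_system(cohort, "cardiac")
  ) %>%
    mutate(venn = venn_category(.data$hepatic, .data$neuromuscular,
                                .data$cardiac))
}
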