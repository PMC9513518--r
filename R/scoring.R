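.n_levels <- c("N0", "N1", "N2", "N3", "unscorable")
.h_levels <- c("H0", "H1", "H2", "H3", "unscorable")
.subtype_levels <- c(
  "perinatal_congenital_neuromuscular", "juvenile_neuromuscular",
  "classic_hepatic", "non_progressive_hepatic",
  "intermediate_neuromuscular", "intermediate_hepatic",
  "mixed", "no_hepatic_no_neuromuscular", "unclassifiable"
)

# Cutoffs in months. "<6 months" and "<5 years" are strict; survival TO the
# cutoff (>=) takes the milder class, matching the scale definitions
# ("survival to >=6 months", "surviving to >=5 years").
.n_cutoff_months <- 6
.h_cutoff_months <- 60

#' Detect severe hepatic features
#'
#' A patient has severe hepatic disease given any reported history of liver
#' failure or synthetic dysfunction; jaundice or hyperbilirubinemia; ascites;
#' varices or gastrointestinal bleed; or splenomegaly with thrombocytopenia
#' (platelets < 150,000/µl, consistent with clinically evident portal
#' hypertension). The newborn-period and heart-failure exclusions apply here
#' exactly as in involvement assessment, so e.g. hyperbilirubinemia limited to
#' the immediate newborn period never counts as severe. Splenomegaly without a
#' documented platelet count below threshold is not severe.
#'
#' @param cohort A cohort tibble.
#' @return Logical vector, one element per patient.
#' @examples
#' has_severe_hepatic_features(
#'   patient_record("L1", findings("splenomegaly", platelet_count = 120000)))
#' @export
has_severe_hepatic_features <- function(cohort) {
  cohort <- as_cohort(cohort)
  map_lgl(cohort$findings, function(fnd) {
    qual <- qualifying_findings(fnd, "hepatic")
    if (nrow(qual) == 0) return(FALSE)
    plain_severe <- qual$code %in% .severe_hepatic_codes
    spleno_severe <- qual$code == "splenomegaly" &
      !is.na(qual$platelet_count) & qual$platelet_count < .platelet_threshold
    any(plain_severe | spleno_severe)
  })
}

# Survival to at least `months` is documented when the patient died at or
# after that age, was followed (alive or otherwise) to at least that age, or
# underwent transplant at or after that age.
.survived_to <- function(cohort, months) {
  death_ok <- !is.na(cohort$age_at_death_months) &
    cohort$age_at_death_months >= months
  fu_ok <- !is.na(cohort$age_at_last_followup_months) &
    cohort$age_at_last_followup_months >= months
  tx_ok <- !is.na(cohort$age_at_transplant_months) &
    cohort$age_at_transplant_months >= months
  death_ok | fu_ok | tx_ok
}

.died_before <- function(cohort, months) {
  cohort$vital_status == "deceased" & !is.na(cohort$age_at_death_months) &
    cohort$age_at_death_months < months
}

#' Score the neuromuscular component (N0-N3)
#'
#' The four-point neuromuscular scale distinguishes patients by onset timing
#' and survival: N3 — onset at or before birth leading to death at <6 months;
#' N2 — onset at or before birth with survival to >=6 months; N1 — onset after
#' birth; N0 — no neuromuscular involvement. Patients with unknown involvement,
#' unreported onset timing, or censoring before the 6-month cutoff are
#' `unscorable` rather than optimistically assigned a milder score.
#'
#' @param cohort A cohort tibble with no prenatal-death rows.
#' @param involvement Character vector of neuromuscular involvement statuses;
#'   computed with [assess_neuromuscular()] when omitted.
#' @return Character vector with values `"N0"`..`"N3"` or `"unscorable"`.
#' @export
score_neuromuscular <- function(cohort, involvement = NULL) {
  cohort <- as_cohort(cohort)
  .check_not_prenatal(cohort, "phenotype scoring")
  if (is.null(involvement)) involvement <- assess_system(cohort, "neuromuscular")
  involvement <- vctrs::vec_recycle(involvement, nrow(cohort))
  early_onset <- cohort$neuromuscular_onset %in% c("prenatal", "at_birth")
  died_lt6 <- .died_before(cohort, .n_cutoff_months)
  surv_ge6 <- .survived_to(cohort, .n_cutoff_months)
  case_when(
    involvement == "absent" ~ "N0",
    involvement == "unknown" ~ "unscorable",
    cohort$neuromuscular_onset == "postnatal" ~ "N1",
    early_onset & died_lt6 ~ "N3",
    early_onset & surv_ge6 ~ "N2",
    TRUE ~ "unscorable"
  )
}

#' Score the hepatic component (H0-H3)
#'
#' The four-point hepatic scale combines severity with transplant/survival
#' outcome: H3 — hepatic involvement with severe features leading to liver
#' transplant (LT) or death at <5 years; H2 — severe features with survival to
#' >=5 years without LT before 5 years (LT at or after 5 years remains H2);
#' H1 — involvement without severe features; H0 — no hepatic involvement.
#' Severely affected patients still alive below the 5-year cutoff without LT
#' are `unscorable` (censored), as are patients with unknown involvement.
#'
#' By default death before 5 years counts toward H3 regardless of its recorded
#' cause; set `require_hepatic_death_attribution = TRUE` to count only deaths
#' flagged `death_attributed_hepatic`.
#'
#' @param cohort A cohort tibble with no prenatal-death rows.
#' @param involvement Character vector of hepatic involvement statuses;
#'   computed with [assess_hepatic()] when omitted.
#' @param require_hepatic_death_attribution Logical (default `FALSE`).
#' @return Character vector with values `"H0"`..`"H3"` or `"unscorable"`.
#' @export
score_hepatic <- function(cohort, involvement = NULL,
                          require_hepatic_death_attribution = FALSE) {
  cohort <- as_cohort(cohort)
  .check_not_prenatal(cohort, "phenotype scoring")
  if (is.null(involvement)) involvement <- assess_system(cohort, "hepatic")
  involvement <- vctrs::vec_recycle(involvement, nrow(cohort))
  severe <- has_severe_hepatic_features(cohort)
  lt_before <- cohort$liver_transplant == "yes" &
    !is.na(cohort$age_at_transplant_months) &
    cohort$age_at_transplant_months < .h_cutoff_months
  death_before <- .died_before(cohort, .h_cutoff_months)
  if (require_hepatic_death_attribution) {
    death_before <- death_before & cohort$death_attributed_hepatic %in% TRUE
  }
  surv_ge60 <- .survived_to(cohort, .h_cutoff_months)
  case_when(
    involvement == "absent" ~ "H0",
    involvement == "unknown" ~ "unscorable",
    !severe ~ "H1",
    lt_before | death_before ~ "H3",
    surv_ge60 ~ "H2",
    TRUE ~ "unscorable"
  )
}

#' Classify a two-part score against the established subtypes
#'
#' Total, single-valued mapping of the (N, H) score combination onto the
#' established GSD IV subtypes and the regions of the 4x4 grid that fall
#' outside them: N3-H0 perinatal-congenital neuromuscular; N1-H0 juvenile
#' neuromuscular; N0-H3 classic hepatic; N0-H1 non-progressive hepatic;
#' N2-H0 / N0-H2 intermediate; N>0 with H>0 mixed; N0-H0 neither hepatic nor
#' neuromuscular (e.g. exclusively cardiac disease); any unscorable component
#' is unclassifiable.
#'
#' @param n_score,h_score Character vectors of component scores, recycled to a
#'   common length.
#' @return Character vector of subtype categories.
#' @examples
#' classify_subtype("N3", "H0")
#' classify_subtype("N1", "H1")
#' @export
classify_subtype <- function(n_score, h_score) {
  len <- max(length(n_score), length(h_score))
  ns <- vctrs::vec_recycle(n_score, len)
  hs <- vctrs::vec_recycle(h_score, len)
  if (!all(ns %in% .n_levels) || !all(hs %in% .h_levels)) {
    abort("scores must be N0-N3 / H0-H3 or 'unscorable'")
  }
  case_when(
    ns == "unscorable" | hs == "unscorable" ~ "unclassifiable",
    ns == "N3" & hs == "H0" ~ "perinatal_congenital_neuromuscular",
    ns == "N2" & hs == "H0" ~ "intermediate_neuromuscular",
    ns == "N1" & hs == "H0" ~ "juvenile_neuromuscular",
    ns == "N0" & hs == "H3" ~ "classic_hepatic",
    ns == "N0" & hs == "H2" ~ "intermediate_hepatic",
    ns == "N0" & hs == "H1" ~ "non_progressive_hepatic",
    ns == "N0" & hs == "H0" ~ "no_hepatic_no_neuromuscular",
    TRUE ~ "mixed"
  )
}

#' Assign two-part phenotype scores to a cohort
#'
#' Composes involvement assessment with the neuromuscular and hepatic scoring
#' scales and classifies each patient's (N, H) combination against the
#' established subtypes. Patients who died in utero are never scored and are
#' dropped by default.
#'
#' @param cohort A cohort tibble.
#' @param drop_prenatal Drop prenatal-death rows (default `TRUE`); with
#'   `FALSE` any prenatal-death row raises an error.
#' @inheritParams score_hepatic
#' @return A tibble with one row per scored patient: `patient_id`, the three
#'   involvement statuses and `venn` category, `severe_hepatic`, `n_score`,
#'   `h_score`, `complete` (neither component unscorable), `score` (the
#'   combined label, e.g. `"N2-H0"`, `NA` when incomplete), and `subtype`.
#' @examples
#' coh <- patient_record(
#'   "L1", findings("hypotonia"), neuromuscular_onset = "at_birth",
#'   vital_status = "deceased", age_at_death_months = 2,
#'   explicit_normal_hepatic = TRUE)
#' score_phenotype(coh)
#' @export
score_phenotype <- function(cohort, drop_prenatal = TRUE,
                            require_hepatic_death_attribution = FALSE) {
  cohort <- as_cohort(cohort)
  if (drop_prenatal) cohort <- filter(cohort, !.data$prenatal_death)
  .check_not_prenatal(cohort, "phenotype scoring")
  inv <- tibble(
    hepatic = assess_system(cohort, "hepatic"),
    neuromuscular = assess_system(cohort, "neuromuscular"),
    cardiac = assess_system(cohort, "cardiac")
  )
  n_score <- score_neuromuscular(cohort, inv$neuromuscular)
  h_score <- score_hepatic(cohort, inv$hepatic,
                           require_hepatic_death_attribution)
  tibble(
    patient_id = cohort$patient_id,
    hepatic = inv$hepatic,
    neuromuscular = inv$neuromuscular,
    cardiac = inv$cardiac,
    venn = venn_category(inv$hepatic, inv$neuromuscular, inv$cardiac),
    severe_hepatic = has_severe_hepatic_features(cohort),
    n_score = n_score,
    h_score = h_score,
    complete = n_score != "unscorable" & h_score != "unscorable",
    score = if_else(n_score != "unscorable" & h_score != "unscorable",
                    paste0(n_score, "-", h_score), NA_character_),
    subtype = classify_subtype(n_score, h_score)
  )
}
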