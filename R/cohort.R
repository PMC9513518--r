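.onset_levels <- c("prenatal", "at_birth", "postnatal", "none_reported",
                   "unknown")
.vital_levels <- c("alive", "deceased", "unknown")
.transplant_levels <- c("yes", "no", "unknown")

.cohort_columns <- c(
  "patient_id", "findings", "neuromuscular_onset", "vital_status",
  "prenatal_death", "age_at_death_months", "age_at_last_followup_months",
  "liver_transplant", "age_at_transplant_months",
  "explicit_normal_hepatic", "explicit_normal_neuromuscular",
  "explicit_normal_cardiac", "death_attributed_hepatic"
)

#' Construct a patient record
#'
#' Builds a one-row cohort tibble describing a single patient. Missingness is
#' explicit throughout: enumerated fields default to `"unknown"`, ages to `NA`,
#' and the per-system explicit-normal flags to `FALSE`. A system counts as
#' affirmatively unaffected only when the source stated normality, so
#' `explicit_normal_*` must be set deliberately — zero recorded findings alone
#' leave the system's involvement unknown.
#'
#' All ages are in months (decimals allowed).
#'
#' @param patient_id Unique identifier string.
#' @param findings A findings tibble, see [findings()].
#' @param neuromuscular_onset One of `"prenatal"`, `"at_birth"`, `"postnatal"`,
#'   `"none_reported"`, `"unknown"`.
#' @param vital_status One of `"alive"`, `"deceased"`, `"unknown"`.
#' @param prenatal_death Logical; patients who died in utero are never assessed
#'   or scored.
#' @param age_at_death_months,age_at_last_followup_months,age_at_transplant_months
#'   Non-negative ages in months or `NA`.
#' @param liver_transplant One of `"yes"`, `"no"`, `"unknown"`.
#' @param explicit_normal_hepatic,explicit_normal_neuromuscular,explicit_normal_cardiac
#'   Logical flags recording that the source affirmed the system was normal at
#'   all reported visits.
#' @param death_attributed_hepatic Logical or `NA`; whether death was
#'   attributed to hepatic disease. Unused by default scoring (see
#'   [score_phenotype()]).
#' @return A one-row `gsd4_cohort` tibble.
#' @examples
#' patient_record("L1", findings("hepatomegaly"), vital_status = "alive")
#' @export
patient_record <- function(patient_id,
                           findings = empty_findings(),
                           neuromuscular_onset = "unknown",
                           vital_status = "unknown",
                           prenatal_death = FALSE,
                           age_at_death_months = NA_real_,
                           age_at_last_followup_months = NA_real_,
                           liver_transplant = "unknown",
                           age_at_transplant_months = NA_real_,
                           explicit_normal_hepatic = FALSE,
                           explicit_normal_neuromuscular = FALSE,
                           explicit_normal_cardiac = FALSE,
                           death_attributed_hepatic = NA) {
  new_cohort(tibble(
    patient_id = as.character(patient_id),
    findings = list(as_tibble(findings)),
    neuromuscular_onset = as.character(neuromuscular_onset),
    vital_status = as.character(vital_status),
    prenatal_death = as.logical(prenatal_death),
    age_at_death_months = as.double(age_at_death_months),
    age_at_last_followup_months = as.double(age_at_last_followup_months),
    liver_transplant = as.character(liver_transplant),
    age_at_transplant_months = as.double(age_at_transplant_months),
    explicit_normal_hepatic = as.logical(explicit_normal_hepatic),
    explicit_normal_neuromuscular = as.logical(explicit_normal_neuromuscular),
    explicit_normal_cardiac = as.logical(explicit_normal_cardiac),
    death_attributed_hepatic = as.logical(death_attributed_hepatic)
  ))
}

new_cohort <- function(x) {
  stopifnot(is.data.frame(x))
  class(x) <- unique(c("gsd4_cohort", class(as_tibble(x))))
  x
}

#' Coerce a data frame to a validated cohort
#'
#' Fills absent columns with their explicit-missing defaults (`"unknown"`
#' enums, `NA` ages, `FALSE` explicit-normal flags), checks the record
#' invariants with [validate_cohort()], and errors on any violation.
#'
#' @param x A data frame with one row per patient; `findings` may be a
#'   list-column of findings tibbles or absent.
#' @return A `gsd4_cohort` tibble.
#' @seealso [patient_record()], [read_cohort()]
#' @export
as_cohort <- function(x) {
  # cohorts built by the package's constructors are valid by construction
  if (inherits(x, "gsd4_cohort")) return(x)
  x <- as_tibble(x)
  if (!"patient_id" %in% names(x)) {
    abort("a cohort requires a 'patient_id' column")
  }
  if (!"findings" %in% names(x)) {
    x$findings <- rep(list(empty_findings()), nrow(x))
  }
  x$findings <- map(x$findings, function(f) {
    if (is.null(f)) return(empty_findings())
    f <- as_tibble(f)
    proto <- empty_findings()
    for (col in setdiff(names(proto), names(f))) {
      f[[col]] <- rep(proto[[col]][NA_integer_], nrow(f))
    }
    f[names(proto)]
  })
  defaults <- list(
    neuromuscular_onset = "unknown", vital_status = "unknown",
    prenatal_death = FALSE, age_at_death_months = NA_real_,
    age_at_last_followup_months = NA_real_, liver_transplant = "unknown",
    age_at_transplant_months = NA_real_, explicit_normal_hepatic = FALSE,
    explicit_normal_neuromuscular = FALSE, explicit_normal_cardiac = FALSE,
    death_attributed_hepatic = NA
  )
  for (col in names(defaults)) {
    d <- defaults[[col]]
    if (!col %in% names(x)) {
      x[[col]] <- rep(d, nrow(x))
    } else if (is.character(d)) {
      v <- as.character(x[[col]])
      v[is.na(v) | v == ""] <- "unknown"
      x[[col]] <- v
    } else if (is.logical(d)) {
      v <- as.logical(x[[col]])
      if (!is.na(d)) v[is.na(v)] <- d
      x[[col]] <- v
    } else {
      x[[col]] <- suppressWarnings(as.double(x[[col]]))
    }
  }
  x$patient_id <- as.character(x$patient_id)
  out <- new_cohort(x[, .cohort_columns])
  v <- validate_cohort(out)
  if (nrow(v) > 0) {
    msgs <- sprintf("  [%s] %s: %s", v$patient_id, v$field, v$message)
    abort(c("invalid cohort:", utils::head(msgs, 10)))
  }
  out
}

#' Validate cohort records against the data-model invariants
#'
#' Checks every record and returns violations as data rather than raising.
#' Invariants include: unique patient ids; valid enumeration values and
#' finding codes; prenatal deaths are deceased with no death age; a death age
#' implies deceased; a transplant implies a transplant age; qualifier flags
#' only on the codes they apply to; positive platelet counts and non-negative
#' ages; and an explicit-normal flag contradicts any surviving qualifying
#' finding in that system (findings removed by the newborn-period or
#' heart-failure exclusions do not contradict it).
#'
#' @param cohort A cohort tibble.
#' @return A tibble with columns `patient_id`, `field`, `message`; zero rows
#'   when every invariant holds.
#' @examples
#' validate_cohort(patient_record("L1", vital_status = "alive"))
#' @export
validate_cohort <- function(cohort) {
  cohort <- as_tibble(cohort)
  out <- list()
  add <- function(ids, field, message) {
    if (length(ids) > 0) {
      out[[length(out) + 1]] <<- tibble(patient_id = ids, field = field,
                                        message = message)
    }
  }
  id <- cohort$patient_id
  add(unique(id[duplicated(id)]), "patient_id", "duplicate patient_id")
  n_empty <- sum(is.na(id) | id == "")
  add(rep("<missing>", n_empty), "patient_id", "empty patient_id")

  add(id[!cohort$neuromuscular_onset %in% .onset_levels],
      "neuromuscular_onset", "invalid onset value")
  add(id[!cohort$vital_status %in% .vital_levels],
      "vital_status", "invalid vital status value")
  add(id[!cohort$liver_transplant %in% .transplant_levels],
      "liver_transplant", "invalid transplant value")

  pren <- cohort$prenatal_death %in% TRUE
  add(id[pren & cohort$vital_status != "deceased"], "prenatal_death",
      "prenatal death requires vital_status 'deceased'")
  add(id[pren & !is.na(cohort$age_at_death_months)], "age_at_death_months",
      "prenatal death must not carry an age at death")
  add(id[!is.na(cohort$age_at_death_months) &
           cohort$vital_status != "deceased"],
      "age_at_death_months", "age at death recorded for a patient not deceased")
  add(id[cohort$liver_transplant == "yes" &
           is.na(cohort$age_at_transplant_months)],
      "age_at_transplant_months", "liver transplant requires an age at transplant")
  for (col in c("age_at_death_months", "age_at_last_followup_months",
                "age_at_transplant_months")) {
    add(id[!is.na(cohort[[col]]) & cohort[[col]] < 0], col,
        "age must be non-negative")
  }

  flags <- cbind(hepatic = cohort$explicit_normal_hepatic %in% TRUE,
                 neuromuscular = cohort$explicit_normal_neuromuscular %in% TRUE,
                 cardiac = cohort$explicit_normal_cardiac %in% TRUE)
  n_rows <- map_dbl(cohort$findings, nrow)
  for (i in which(n_rows > 0 | rowSums(flags) > 0)) {
    fnd <- cohort$findings[[i]]
    if (nrow(fnd) > 0) {
      bad <- setdiff(fnd$code, .all_codes())
      add(rep(id[i], length(bad)), "findings",
          paste0("unknown finding code '", bad, "'"))
      nb <- fnd$code[fnd$newborn_period_only %in% TRUE &
                       !fnd$code %in% c("fasting_hypoglycemia",
                                        "hyperbilirubinemia")]
      add(rep(id[i], length(nb)), "findings", paste0(
        "newborn_period_only only applies to fasting_hypoglycemia/hyperbilirubinemia, not '",
        nb, "'"))
      hf <- fnd$code[fnd$heart_failure_context_only %in% TRUE &
                       fnd$code != "ascites"]
      add(rep(id[i], length(hf)), "findings",
          paste0("heart_failure_context_only only applies to ascites, not '",
                 hf, "'"))
      if (any(!is.na(fnd$platelet_count) & fnd$platelet_count <= 0)) {
        add(id[i], "findings", "platelet_count must be positive")
      }
      if (any(!is.na(fnd$age_first_observed_months) &
                fnd$age_first_observed_months < 0)) {
        add(id[i], "findings", "age_first_observed_months must be non-negative")
      }
      for (sys in c("hepatic", "neuromuscular", "cardiac")) {
        if (flags[i, sys] && nrow(qualifying_findings(fnd, sys)) > 0) {
          add(id[i], paste0("explicit_normal_", sys),
              sprintf("explicit-normal %s contradicts a qualifying %s finding",
                      sys, sys))
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(patient_id = character(), field = character(),
                  message = character()))
  }
  bind_rows(out)
}

#' @export
print.gsd4_cohort <- function(x, ...) {
  cat(sprintf("<gsd4_cohort: %d patients>\n", nrow(x)))
  NextMethod()
}
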