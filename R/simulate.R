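# Synthetic cohort generation. Each requested (N, H, cardiac) cell is
# realized with the minimal sufficient finding set — one qualifying finding
# per involved system plus explicit-normal flags for uninvolved systems — and
# an outcome (onset timing, survival, transplant) engineered so the scoring
# pipeline recovers exactly that cell. Ages are drawn uniformly from bin
# interiors, never on cutoff boundaries, so recovery is robust to boundary
# conventions. All randomness flows through one seed (R's default
# Mersenne-Twister generator), so a fixed seed gives identical cohorts.

.cardiac_levels <- c("present", "absent", "unknown")

#' Specify a synthetic cohort
#'
#' A cohort specification lists how many patients to generate in each
#' complete (N, H, cardiac) cell, how many additional unscorable patients to
#' add, optional per-field missingness rates applied after generation, and the
#' random seed.
#'
#' The cell (N3, H2) is the one logically infeasible combination — N3 requires
#' death before 6 months while H2 requires survival to 5 years — and is
#' rejected here.
#'
#' @param cells A data frame with columns `n_score` (`"N0"`..`"N3"`),
#'   `h_score` (`"H0"`..`"H3"`), `cardiac` (`"present"`, `"absent"`,
#'   `"unknown"`), and non-negative integer `count`.
#' @param n_unscorable Number of extra patients with neuromuscular involvement
#'   of unreported onset and no hepatic or cardiac data (unscorable and not
#'   tri-assessable).
#' @param missingness Named numeric vector of per-field blanking
#'   probabilities in \[0, 1\] (see [perturb_missingness()] for field names),
#'   or `NULL`.
#' @param seed Integer seed.
#' @return A `gsd4_cohort_spec`.
#' @examples
#' cohort_spec(data.frame(n_score = "N3", h_score = "H0",
#'                        cardiac = "absent", count = 2), seed = 1)
#' @export
cohort_spec <- function(cells, n_unscorable = 0, missingness = NULL,
                        seed = NULL) {
  cells <- as_tibble(cells)
  required <- c("n_score", "h_score", "cardiac", "count")
  if (!all(required %in% names(cells))) {
    abort(sprintf("spec cells need columns: %s", paste(required, collapse = ", ")))
  }
  if (!all(cells$n_score %in% .n_levels[1:4]) ||
      !all(cells$h_score %in% .h_levels[1:4])) {
    abort("cell scores must be complete levels N0-N3 / H0-H3")
  }
  if (!all(cells$cardiac %in% .cardiac_levels)) {
    abort("cell cardiac status must be present/absent/unknown")
  }
  if (any(is.na(cells$count) | cells$count < 0 |
            cells$count != round(cells$count))) {
    abort("cell counts must be non-negative integers")
  }
  bad <- cells$n_score == "N3" & cells$h_score == "H2" & cells$count > 0
  if (any(bad)) {
    abort(paste("infeasible cell (N3, H2): death before 6 months cannot",
                "coexist with survival to 5 years"))
  }
  if (n_unscorable < 0 || n_unscorable != round(n_unscorable)) {
    abort("n_unscorable must be a non-negative integer")
  }
  if (!is.null(missingness)) {
    if (is.null(names(missingness)) || any(!nzchar(names(missingness)))) {
      abort("missingness rates must be named")
    }
    if (any(missingness < 0 | missingness > 1)) {
      abort("missingness rates must lie in [0, 1]")
    }
  }
  structure(
    list(cells = mutate(cells, count = as.integer(.data$count)),
         n_unscorable = as.integer(n_unscorable),
         missingness = missingness,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "gsd4_cohort_spec"
  )
}

#' @export
print.gsd4_cohort_spec <- function(x, ...) {
  cat(sprintf("<gsd4_cohort_spec: %d scorable + %d unscorable patients, seed %s>\n",
              sum(x$cells$count), x$n_unscorable,
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' Read / write a cohort specification as YAML
#'
#' The on-disk format has top-level keys `cells` (a list of
#' `{n, h, cardiac, count}` entries), `n_unscorable`, `seed`, and
#' `missingness` (a map of field name to rate).
#'
#' @param path YAML file path.
#' @return A `gsd4_cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$cells)) abort(sprintf("%s: spec has no 'cells'", path))
  cells <- bind_rows(map(y$cells, function(cell) {
    tibble(n_score = cell$n %||% cell$n_score %||% NA_character_,
           h_score = cell$h %||% cell$h_score %||% NA_character_,
           cardiac = cell$cardiac %||% "unknown",
           count = cell$count %||% NA_integer_)
  }))
  cohort_spec(cells,
              n_unscorable = y$n_unscorable %||% 0,
              missingness = if (is.null(y$missingness)) NULL
                            else unlist(y$missingness),
              seed = y$seed)
}

#' @rdname read_cohort_spec
#' @param spec A `gsd4_cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "gsd4_cohort_spec"))
  y <- list(
    cells = map(seq_len(nrow(spec$cells)), function(i) {
      r <- spec$cells[i, ]
      list(n = r$n_score, h = r$h_score, cardiac = r$cardiac,
           count = r$count)
    }),
    n_unscorable = spec$n_unscorable,
    missingness = as.list(spec$missingness),
    seed = spec$seed
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

# -- record construction primitives -----------------------------------------

.nm_fields <- function(level, embellish = FALSE) {
  switch(level,
    N0 = list(findings = empty_findings(), onset = "none_reported",
              normal = TRUE),
    N1 = list(
      findings = findings("weakness_or_exercise_intolerance",
                          age_first_observed_months = runif(1, 7, 60)),
      onset = "postnatal", normal = FALSE),
    N2 = ,
    N3 = list(
      findings = findings(
        c("hypotonia",
          if (level == "N3" || embellish) "ventilator_dependent_respiratory_weakness",
          if (embellish) "contractures"),
        age_first_observed_months = 0),
      onset = "at_birth", normal = FALSE),
    onset_unknown = list(findings = findings("hypotonia"), onset = "unknown",
                         normal = FALSE),
    unknown = list(findings = empty_findings(), onset = "unknown",
                   normal = FALSE)
  )
}

.hep_fields <- function(level, embellish = FALSE) {
  switch(level,
    H0 = list(findings = empty_findings(), normal = TRUE),
    H1 = list(
      findings = findings(c("hepatomegaly", if (embellish) "elevated_alt")),
      normal = FALSE),
    H2 = list(
      findings = bind_rows(
        findings("splenomegaly", platelet_count = runif(1, 60000, 140000)),
        findings("hepatomegaly")),
      normal = FALSE),
    H3 = list(
      findings = findings(c("liver_failure", "jaundice", "hepatomegaly")),
      normal = FALSE),
    unknown = list(findings = empty_findings(), normal = FALSE)
  )
}

.cardiac_fields <- function(level) {
  switch(level,
    present = list(findings = findings("cardiomyopathy"), normal = FALSE),
    absent = list(findings = empty_findings(), normal = TRUE),
    unknown = list(findings = empty_findings(), normal = FALSE)
  )
}

# Assemble one synthetic patient. `outcome` is a list:
#   list(type = "death", age = months [, hepatic = TRUE])
#   list(type = "alive", fu = months)
#   list(type = "lt", tx = months, fu = months)   (alive after transplant)
#   list(type = "vital_unknown" [, fu = months])
#   list(type = "prenatal")
synth_patient <- function(id, nm = "unknown", hep = "unknown",
                          cardiac = "unknown", outcome = list(type = "alive",
                                                              fu = 60),
                          embellish = FALSE) {
  if (identical(outcome$type, "prenatal")) {
    return(patient_record(id, prenatal_death = TRUE,
                          vital_status = "deceased"))
  }
  nmf <- .nm_fields(nm, embellish)
  hpf <- .hep_fields(hep, embellish)
  cdf <- .cardiac_fields(cardiac)
  fnd <- bind_rows(nmf$findings, hpf$findings, cdf$findings)
  args <- list(
    patient_id = id, findings = fnd, neuromuscular_onset = nmf$onset,
    explicit_normal_hepatic = hpf$normal,
    explicit_normal_neuromuscular = nmf$normal,
    explicit_normal_cardiac = cdf$normal
  )
  args <- switch(outcome$type,
    death = c(args, list(vital_status = "deceased",
                         age_at_death_months = outcome$age,
                         death_attributed_hepatic = outcome$hepatic %||% NA)),
    alive = c(args, list(vital_status = "alive",
                         age_at_last_followup_months = outcome$fu)),
    lt = c(args, list(vital_status = "alive", liver_transplant = "yes",
                      age_at_transplant_months = outcome$tx,
                      age_at_last_followup_months = outcome$fu)),
    vital_unknown = c(args, list(vital_status = "unknown",
                                 age_at_last_followup_months =
                                   outcome$fu %||% NA_real_)),
    abort(sprintf("unknown outcome type '%s'", outcome$type))
  )
  do.call(patient_record, args)
}

# Outcome consistent with a complete (N, H) cell; ages drawn off-boundary.
.cell_outcome <- function(n_score, h_score) {
  if (n_score == "N3") {
    list(type = "death", age = runif(1, 0.5, 3.5))
  } else if (h_score == "H3") {
    tx <- runif(1, 12, 48)
    list(type = "lt", tx = tx, fu = tx + runif(1, 12, 60))
  } else if (h_score == "H2") {
    list(type = "alive", fu = runif(1, 66, 200))
  } else {
    list(type = "alive", fu = runif(1, 12, 180))
  }
}

#' Generate a synthetic cohort from a specification
#'
#' Emits, for every requested cell, records engineered so that
#' [score_phenotype()] assigns exactly that (N, H) combination and
#' [assess_cardiac()] returns the requested cardiac status. With zero
#' missingness the pipeline recovers the spec's cell counts exactly; the same
#' seed always yields an identical cohort. Generated records always pass
#' [validate_cohort()].
#'
#' @param spec A `gsd4_cohort_spec`.
#' @param seed Integer seed; defaults to the spec's seed. When both are
#'   `NULL` a seed is drawn and reported via a message.
#' @param embellish Add extra consistent findings per involved system
#'   (stress-tests permutation invariance of assessment); default `FALSE`
#'   keeps the minimal sufficient finding set.
#' @return A `gsd4_cohort` tibble.
#' @examples
#' spec <- cohort_spec(data.frame(n_score = "N3", h_score = "H0",
#'                                cardiac = "absent", count = 2), seed = 7)
#' coh <- generate_cohort(spec)
#' score_phenotype(coh)[, c("n_score", "h_score")]
#' @export
generate_cohort <- function(spec, seed = NULL, embellish = FALSE) {
  stopifnot(inherits(spec, "gsd4_cohort_spec"))
  seed <- seed %||% spec$seed
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1)
    inform(sprintf("no seed supplied; using auto-generated seed %d", seed))
  }
  cells <- filter(spec$cells, .data$count > 0)
  withr::with_seed(seed, {
    rows <- list()
    idx <- 0
    for (i in seq_len(nrow(cells))) {
      cell <- cells[i, ]
      for (k in seq_len(cell$count)) {
        idx <- idx + 1
        rows[[idx]] <- synth_patient(
          sprintf("S%04d", idx),
          nm = cell$n_score, hep = cell$h_score, cardiac = cell$cardiac,
          outcome = .cell_outcome(cell$n_score, cell$h_score),
          embellish = embellish
        )
      }
    }
    for (k in seq_len(spec$n_unscorable)) {
      idx <- idx + 1
      rows[[idx]] <- synth_patient(
        sprintf("S%04d", idx), nm = "onset_unknown", hep = "unknown",
        cardiac = "unknown", outcome = list(type = "alive",
                                            fu = runif(1, 7, 60)))
    }
    out <- if (idx == 0) {
      as_cohort(tibble(patient_id = character()))
    } else {
      new_cohort(bind_rows(rows))
    }
    if (!is.null(spec$missingness)) {
      out <- perturb_missingness(out, spec$missingness,
                                 seed = sample.int(2^31 - 1, 1))
    }
    out
  })
}

.missingness_fields <- c(
  "findings", "neuromuscular_onset", "vital_status", "age_at_death_months",
  "age_at_last_followup_months", "liver_transplant",
  "explicit_normal_hepatic", "explicit_normal_neuromuscular",
  "explicit_normal_cardiac"
)

#' Degrade a cohort by blanking fields at random
#'
#' Independently resets fields to their unknown states at the given per-field
#' rates. Blanking never fabricates findings or flips a value to a different
#' known value, so the number of scorable patients can only decrease.
#' Prenatal-death records are left untouched (their vital status is
#' structural). Blanking `vital_status` or `liver_transplant` also clears the
#' dependent age so record invariants keep holding.
#'
#' @param cohort A cohort tibble.
#' @param rates Named numeric vector of probabilities in \[0, 1\]; names from
#'   `findings`, `neuromuscular_onset`, `vital_status`, `age_at_death_months`,
#'   `age_at_last_followup_months`, `liver_transplant`,
#'   `explicit_normal_hepatic`, `explicit_normal_neuromuscular`,
#'   `explicit_normal_cardiac`.
#' @param seed Integer seed.
#' @return A `gsd4_cohort` tibble of the same size.
#' @export
perturb_missingness <- function(cohort, rates, seed) {
  cohort <- as_cohort(cohort)
  if (length(rates) == 0) return(cohort)
  if (is.null(names(rates)) || !all(names(rates) %in% .missingness_fields)) {
    abort(sprintf("missingness fields must be among: %s",
                  paste(.missingness_fields, collapse = ", ")))
  }
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  n <- nrow(cohort)
  withr::with_seed(as.integer(seed), {
    for (field in names(rates)) {
      hit <- runif(n) < rates[[field]] & !cohort$prenatal_death
      if (!any(hit)) next
      if (field == "findings") {
        cohort$findings[hit] <- list(empty_findings())
      } else if (field == "neuromuscular_onset") {
        cohort$neuromuscular_onset[hit] <- "unknown"
      } else if (field == "vital_status") {
        cohort$vital_status[hit] <- "unknown"
        cohort$age_at_death_months[hit] <- NA_real_
      } else if (field == "liver_transplant") {
        cohort$liver_transplant[hit] <- "unknown"
        cohort$age_at_transplant_months[hit] <- NA_real_
      } else if (field %in% c("age_at_death_months",
                              "age_at_last_followup_months")) {
        cohort[[field]][hit] <- NA_real_
      } else {
        cohort[[field]][hit] <- FALSE
      }
    }
  })
  new_cohort(cohort)
}
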