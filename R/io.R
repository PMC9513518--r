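# Cohort serialization.
#
# CSV dialect: UTF-8, comma-separated, one row per patient. The findings
# column is a semicolon-separated list of tokens `code[:qualifier=value]...`
# with qualifiers newborn_period_only, heart_failure_context_only (true/false),
# platelet_count and age_first_observed_months (numbers), e.g.
# "splenomegaly:platelet_count=120000;hypotonia:age_first_observed_months=0".
#
# JSON: an array of patient objects; findings as an array of objects; absent
# fields are omitted and map back to the explicit "unknown" defaults on read.

.findings_qualifiers <- c("newborn_period_only", "heart_failure_context_only",
                          "platelet_count", "age_first_observed_months")

encode_findings <- function(fnd) {
  if (is.null(fnd) || nrow(fnd) == 0) return("")
  tokens <- map_chr(seq_len(nrow(fnd)), function(i) {
    row <- fnd[i, ]
    tok <- row$code
    if (isTRUE(row$newborn_period_only)) {
      tok <- paste0(tok, ":newborn_period_only=true")
    }
    if (isTRUE(row$heart_failure_context_only)) {
      tok <- paste0(tok, ":heart_failure_context_only=true")
    }
    if (!is.na(row$platelet_count)) {
      tok <- paste0(tok, ":platelet_count=",
                    format(row$platelet_count, scientific = FALSE,
                           trim = TRUE, digits = 17))
    }
    if (!is.na(row$age_first_observed_months)) {
      tok <- paste0(tok, ":age_first_observed_months=",
                    format(row$age_first_observed_months,
                           scientific = FALSE, trim = TRUE, digits = 17))
    }
    tok
  })
  paste(tokens, collapse = ";")
}

decode_findings <- function(s, patient_id = "?") {
  if (is.na(s) || !nzchar(trimws(s))) return(empty_findings())
  tokens <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  rows <- map(tokens, function(tok) {
    parts <- strsplit(trimws(tok), ":", fixed = TRUE)[[1]]
    code <- parts[1]
    out <- list(code = code, newborn_period_only = FALSE,
                heart_failure_context_only = FALSE,
                platelet_count = NA_real_, age_first_observed_months = NA_real_)
    for (kv in parts[-1]) {
      pair <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(pair) != 2 || !pair[1] %in% .findings_qualifiers) {
        abort(sprintf("patient '%s': malformed finding qualifier '%s'",
                      patient_id, kv))
      }
      val <- pair[2]
      if (pair[1] %in% c("newborn_period_only", "heart_failure_context_only")) {
        out[[pair[1]]] <- tolower(val) %in% c("true", "1", "yes")
      } else {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) {
          abort(sprintf("patient '%s': non-numeric value in qualifier '%s'",
                        patient_id, kv))
        }
        out[[pair[1]]] <- num
      }
    }
    as_tibble(out)
  })
  bind_rows(rows)
}

#' Read a cohort from CSV or JSON
#'
#' Parses and validates a cohort file. Fields absent from the input map to the
#' explicit `"unknown"` states (never silently to a negative finding); schema
#' or invariant violations raise an error naming the offending patient and
#' field.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; the default guesses from the file
#'   extension.
#' @return A validated `gsd4_cohort` tibble.
#' @seealso [write_cohort()] for the round-trip guarantee and the on-disk
#'   schema.
#' @export
read_cohort <- function(path, format = c("auto", "csv", "json")) {
  format <- arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "csv") {
    df <- readr::read_csv(
      path, col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE
    )
    if (!"patient_id" %in% names(df)) {
      abort(sprintf("%s: missing required column 'patient_id'", path))
    }
    if ("findings" %in% names(df)) {
      fl <- map2(df$findings, df$patient_id, ~decode_findings(.x, .y))
    } else {
      fl <- rep(list(empty_findings()), nrow(df))
    }
    df$findings <- fl
    as_cohort(df)
  } else {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!is.list(recs)) abort(sprintf("%s: expected a JSON array of records", path))
    rows <- imap(recs, function(rec, i) {
      if (is.null(rec$patient_id)) {
        abort(sprintf("%s: record %d: missing patient_id", path, i))
      }
      fnd <- if (is.null(rec$findings)) {
        empty_findings()
      } else {
        bind_rows(map(rec$findings, function(f) {
          tibble(
            code = f$code %||% NA_character_,
            newborn_period_only = isTRUE(f$newborn_period_only),
            heart_failure_context_only = isTRUE(f$heart_failure_context_only),
            platelet_count = as.double(f$platelet_count %||% NA_real_),
            age_first_observed_months =
              as.double(f$age_first_observed_months %||% NA_real_)
          )
        }))
      }
      tibble(
        patient_id = as.character(rec$patient_id),
        findings = list(fnd),
        neuromuscular_onset = as.character(rec$neuromuscular_onset %||% "unknown"),
        vital_status = as.character(rec$vital_status %||% "unknown"),
        prenatal_death = isTRUE(rec$prenatal_death),
        age_at_death_months = as.double(rec$age_at_death_months %||% NA_real_),
        age_at_last_followup_months =
          as.double(rec$age_at_last_followup_months %||% NA_real_),
        liver_transplant = as.character(rec$liver_transplant %||% "unknown"),
        age_at_transplant_months =
          as.double(rec$age_at_transplant_months %||% NA_real_),
        explicit_normal_hepatic = isTRUE(rec$explicit_normal_hepatic),
        explicit_normal_neuromuscular = isTRUE(rec$explicit_normal_neuromuscular),
        explicit_normal_cardiac = isTRUE(rec$explicit_normal_cardiac),
        death_attributed_hepatic =
          as.logical(rec$death_attributed_hepatic %||% NA)
      )
    })
    as_cohort(bind_rows(rows))
  }
}

#' Write a cohort to CSV or JSON
#'
#' Serializes losslessly: `read_cohort(write_cohort(x, path), ...)` returns a
#' cohort identical field-for-field to `x`, in either format, and the CSV and
#' JSON serializations of one cohort parse to equal cohorts.
#'
#' @param cohort A `gsd4_cohort` (or coercible data frame).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("auto", "csv", "json")) {
  format <- arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  cohort <- as_cohort(cohort)
  if (format == "csv") {
    flat <- as_tibble(cohort) %>%
      mutate(findings = map_chr(.data$findings, encode_findings))
    readr::write_csv(flat, path, na = "", progress = FALSE)
  } else {
    recs <- map(seq_len(nrow(cohort)), function(i) {
      r <- as_tibble(cohort)[i, ]
      rec <- list(patient_id = r$patient_id)
      fnd <- r$findings[[1]]
      if (nrow(fnd) > 0) {
        rec$findings <- map(seq_len(nrow(fnd)), function(j) {
          f <- as.list(fnd[j, ])
          f <- f[!map_lgl(f, ~is.na(.x) || isFALSE(.x))]
          f
        })
      }
      scalars <- list(
        neuromuscular_onset = r$neuromuscular_onset,
        vital_status = r$vital_status,
        prenatal_death = r$prenatal_death,
        age_at_death_months = r$age_at_death_months,
        age_at_last_followup_months = r$age_at_last_followup_months,
        liver_transplant = r$liver_transplant,
        age_at_transplant_months = r$age_at_transplant_months,
        explicit_normal_hepatic = r$explicit_normal_hepatic,
        explicit_normal_neuromuscular = r$explicit_normal_neuromuscular,
        explicit_normal_cardiac = r$explicit_normal_cardiac,
        death_attributed_hepatic = r$death_attributed_hepatic
      )
      keep_it <- !map_lgl(scalars, ~ (is.logical(.x) && is.na(.x)) ||
                            (is.numeric(.x) && is.na(.x)))
      c(rec, scalars[keep_it])
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
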