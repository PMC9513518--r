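#' Build a full cohort report
#'
#' Composes the score matrix, subtype-consistency fraction, Venn summary,
#' per-system prevalence, and survival summary into one deterministic report
#' object with JSON (machine) and markdown (human) renderings.
#'
#' @param cohort A cohort tibble.
#' @param require_hepatic_death_attribution Passed to the hepatic scorer.
#' @return A `gsd4_report` list with elements `n_patients`,
#'   `n_prenatal_deaths`, `score_matrix`, `subtype_consistency`, `venn`,
#'   `prevalence`, `survival`.
#' @seealso [report_markdown()], [report_to_json()], [tidy.gsd4_report()],
#'   [glance.gsd4_report()]
#' @export
build_report <- function(cohort, require_hepatic_death_attribution = FALSE) {
  cohort <- as_cohort(cohort)
  sm <- score_matrix(cohort, require_hepatic_death_attribution)
  consistency <- if (sm$n_scored > 0) {
    subtype_consistency(sm)
  } else {
    tibble(n_consistent = 0L, n_scored = 0L, fraction = NA_real_,
           percent = NA_real_)
  }
  structure(
    list(
      n_patients = nrow(cohort),
      n_prenatal_deaths = sum(cohort$prenatal_death),
      score_matrix = sm,
      subtype_consistency = consistency,
      venn = venn_summary(cohort),
      prevalence = involvement_prevalence(cohort),
      survival = survival_summary(cohort)
    ),
    class = "gsd4_report"
  )
}

#' @export
print.gsd4_report <- function(x, ...) {
  cat(report_markdown(x))
  invisible(x)
}

#' Render a cohort report as markdown
#'
#' @param report A `gsd4_report`.
#' @return A single markdown string.
#' @export
report_markdown <- function(report) {
  stopifnot(inherits(report, "gsd4_report"))
  fmt_pct <- function(p) if_else(is.na(p), "-", sprintf("%.1f%%", p))
  lines <- c(
    "# GSD IV cohort report", "",
    sprintf("- patients: %d (prenatal deaths: %d)", report$n_patients,
            report$n_prenatal_deaths),
    sprintf("- complete (N, H) scores: %d; unscorable: %d",
            report$score_matrix$n_scored, report$score_matrix$n_unscored),
    sprintf("- consistent with an established subtype: %d/%d (%s)",
            report$subtype_consistency$n_consistent,
            report$subtype_consistency$n_scored,
            fmt_pct(report$subtype_consistency$percent)),
    "", "## Score matrix (rows N0-N3, columns H0-H3)", "")
  wide <- tidyr::pivot_wider(report$score_matrix$counts,
                             names_from = "h_score", values_from = "count")
  hdr <- paste0("| ", paste(names(wide), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(wide)), collapse = "|"), "|")
  rows <- map_chr(seq_len(nrow(wide)),
                  ~paste0("| ", paste(unlist(wide[.x, ]), collapse = " | "), " |"))
  lines <- c(lines, hdr, sep, rows, "",
             sprintf("## Tri-system Venn (n = %d assessable, %d not assessable)",
                     report$venn$n_assessable, report$venn$n_not_assessable), "")
  vn <- mutate(report$venn$counts,
               percent = .pct(.data$count, report$venn$n_assessable))
  lines <- c(lines, "| category | n | % |", "|---|---|---|",
             map_chr(seq_len(nrow(vn)), ~sprintf("| %s | %d | %s |",
                                                 vn$category[.x], vn$count[.x],
                                                 fmt_pct(vn$percent[.x]))),
             "", "## Involvement prevalence", "",
             "| system | present | assessable | % |", "|---|---|---|---|",
             map_chr(seq_len(nrow(report$prevalence)), function(i) {
               p <- report$prevalence[i, ]
               sprintf("| %s | %d | %d | %s |", p$system, p$n_present,
                       p$n_assessable, fmt_pct(p$percent))
             }),
             "", "## Survival", "",
             sprintf("- known vital status: %d (alive %d, %s; deceased %d, %s)",
                     report$survival$n_known_status, report$survival$n_alive,
                     fmt_pct(report$survival$percent_alive),
                     report$survival$n_deceased,
                     fmt_pct(report$survival$percent_deceased)),
             sprintf("- deaths at unknown age: %d",
                     report$survival$n_death_age_unknown),
             "", "| death-timing cluster | n | % of deaths |", "|---|---|---|",
             map_chr(seq_len(nrow(report$survival$cluster_bins)), function(i) {
               b <- report$survival$cluster_bins[i, ]
               sprintf("| %s | %d | %s |", b$bin, b$count,
                       fmt_pct(b$percent_of_deaths))
             }), "")
  paste(lines, collapse = "\n")
}

#' @describeIn build_report Long tidy tibble of every count in the report,
#'   with columns `section`, `metric`, `count`, `denominator`, `fraction`.
#' @param x A `gsd4_report`.
#' @param ... Unused.
#' @export
tidy.gsd4_report <- function(x, ...) {
  sm <- x$score_matrix
  bind_rows(
    mutate(tidy(sm),
           section = "score_matrix", metric = .data$score,
           denominator = sm$n_scored) %>%
      select("section", "metric", "count", "denominator"),
    tibble(section = "score_matrix", metric = "unscorable",
           count = sm$n_unscored, denominator = NA_integer_),
    mutate(x$venn$counts, section = "venn", metric = .data$category,
           denominator = x$venn$n_assessable) %>%
      select("section", "metric", "count", "denominator"),
    tibble(section = "venn", metric = "not_assessable",
           count = x$venn$n_not_assessable, denominator = NA_integer_),
    mutate(x$prevalence, section = "prevalence", metric = .data$system,
           count = .data$n_present, denominator = .data$n_assessable) %>%
      select("section", "metric", "count", "denominator"),
    tibble(section = "survival",
           metric = c("alive", "deceased"),
           count = c(x$survival$n_alive, x$survival$n_deceased),
           denominator = x$survival$n_known_status),
    mutate(x$survival$cluster_bins, section = "deaths", metric = .data$bin,
           denominator = x$survival$n_deceased) %>%
      select("section", "metric", "count", "denominator"),
    tibble(section = "subtype_consistency", metric = "established_subtype",
           count = x$subtype_consistency$n_consistent,
           denominator = x$subtype_consistency$n_scored)
  ) %>%
    mutate(count = as.integer(.data$count),
           denominator = as.integer(.data$denominator),
           fraction = if_else(!is.na(.data$denominator) & .data$denominator > 0,
                              .data$count / .data$denominator, NA_real_))
}

#' @describeIn build_report One-row headline summary: cohort size, scored
#'   count, established-subtype percentage, per-system prevalence percentages,
#'   deceased percentage.
#' @export
glance.gsd4_report <- function(x, ...) {
  prev <- function(sys) {
    x$prevalence$percent[x$prevalence$system == sys]
  }
  tibble(
    n_patients = x$n_patients,
    n_scored = x$score_matrix$n_scored,
    pct_established_subtype = x$subtype_consistency$percent,
    n_venn_assessable = x$venn$n_assessable,
    pct_hepatic = prev("hepatic"),
    pct_neuromuscular = prev("neuromuscular"),
    pct_cardiac = prev("cardiac"),
    pct_deceased = x$survival$percent_deceased
  )
}

#' Serialize a cohort report to JSON
#'
#' The JSON form round-trips: [report_from_json()] restores an identical
#' report object.
#'
#' @param report A `gsd4_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "gsd4_report"))
  payload <- list(
    n_patients = report$n_patients,
    n_prenatal_deaths = report$n_prenatal_deaths,
    score_matrix = list(
      counts = report$score_matrix$counts,
      n_scored = report$score_matrix$n_scored,
      n_unscored = report$score_matrix$n_unscored
    ),
    subtype_consistency = report$subtype_consistency,
    venn = list(counts = report$venn$counts,
                n_assessable = report$venn$n_assessable,
                n_not_assessable = report$venn$n_not_assessable),
    prevalence = report$prevalence,
    survival = unclass(report$survival)
  )
  if (is.null(path)) {
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null",
                     pretty = TRUE)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(path)
  }
}

#' Restore a cohort report from JSON
#'
#' @param path Path to a JSON file written by [report_to_json()], or a JSON
#'   string.
#' @return A `gsd4_report`.
#' @export
report_from_json <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  as_int_tbl <- function(df) mutate(as_tibble(df),
                                    count = as.integer(.data$count))
  structure(
    list(
      n_patients = as.integer(p$n_patients),
      n_prenatal_deaths = as.integer(p$n_prenatal_deaths),
      score_matrix = structure(
        list(counts = as_int_tbl(p$score_matrix$counts),
             n_scored = as.integer(p$score_matrix$n_scored),
             n_unscored = as.integer(p$score_matrix$n_unscored)),
        class = "gsd4_score_matrix"),
      subtype_consistency = as_tibble(p$subtype_consistency) %>%
        mutate(across(c("n_consistent", "n_scored"), as.integer)),
      venn = structure(
        list(counts = as_int_tbl(p$venn$counts),
             n_assessable = as.integer(p$venn$n_assessable),
             n_not_assessable = as.integer(p$venn$n_not_assessable)),
        class = "gsd4_venn_summary"),
      prevalence = as_tibble(p$prevalence) %>%
        mutate(across(c("n_assessable", "n_present"), as.integer)),
      survival = structure(
        list(n_known_status = as.integer(p$survival$n_known_status),
             n_alive = as.integer(p$survival$n_alive),
             n_deceased = as.integer(p$survival$n_deceased),
             n_death_age_unknown = as.integer(p$survival$n_death_age_unknown),
             percent_deceased = as.double(p$survival$percent_deceased),
             percent_alive = as.double(p$survival$percent_alive),
             death_bins = as_int_tbl(p$survival$death_bins),
             cluster_bins = as_int_tbl(p$survival$cluster_bins)),
        class = "gsd4_survival_summary")
    ),
    class = "gsd4_report"
  )
}

#' Write the score matrix as TSV
#'
#' @param report A `gsd4_report` or `gsd4_score_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_matrix_tsv <- function(report, path) {
  sm <- if (inherits(report, "gsd4_report")) report$score_matrix else report
  stopifnot(inherits(sm, "gsd4_score_matrix"))
  readr::write_tsv(tidy(sm), path, progress = FALSE)
  invisible(path)
}
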