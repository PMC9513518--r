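# Cohort-level aggregation. All percentages are rendered half-up at one
# decimal; fractions are stored exactly and recomputed from counts.

#' Round half-up
#'
#' Rounds to `digits` decimals with ties away from zero (the convention used
#' when rendering report percentages), unlike base `round()`'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.pct <- function(num, den) {
  n <- max(length(num), length(den))
  num <- rep_len(num, n)
  den <- rep_len(den, n)
  out <- rep(NA_real_, n)
  ok <- !is.na(den) & den > 0 & !is.na(num)
  out[ok] <- round_half_up(100 * num[ok] / den[ok], 1)
  out
}

.scored_or_scores <- function(cohort, require_hepatic_death_attribution = FALSE) {
  if (is.data.frame(cohort) && all(c("n_score", "h_score") %in% names(cohort))) {
    return(as_tibble(cohort))
  }
  score_phenotype(cohort, drop_prenatal = TRUE,
                  require_hepatic_death_attribution =
                    require_hepatic_death_attribution)
}

#' Tabulate the 4x4 matrix of (N, H) score combinations
#'
#' Counts complete two-part scores over the 4x4 grid. Prenatal deaths are
#' excluded; patients whose score is incomplete are tallied in `n_unscored`.
#'
#' @param cohort A cohort tibble, or a per-patient score table from
#'   [score_phenotype()].
#' @param require_hepatic_death_attribution Passed to [score_phenotype()] when
#'   scoring is run here.
#' @return A `gsd4_score_matrix`: list with `counts` (tibble of `n_score`,
#'   `h_score`, `count` over all 16 complete combinations), `n_scored`, and
#'   `n_unscored`.
#' @export
score_matrix <- function(cohort, require_hepatic_death_attribution = FALSE) {
  scores <- .scored_or_scores(cohort, require_hepatic_death_attribution)
  grid <- tidyr::expand_grid(n_score = .n_levels[1:4], h_score = .h_levels[1:4])
  complete <- filter(scores, .data$n_score != "unscorable",
                     .data$h_score != "unscorable")
  counts <- complete %>%
    count(.data$n_score, .data$h_score, name = "count") %>%
    full_join(grid, by = c("n_score", "h_score")) %>%
    mutate(count = if_else(is.na(.data$count), 0L, as.integer(.data$count))) %>%
    arrange(match(.data$n_score, .n_levels), match(.data$h_score, .h_levels))
  structure(
    list(counts = counts,
         n_scored = nrow(complete),
         n_unscored = nrow(scores) - nrow(complete)),
    class = "gsd4_score_matrix"
  )
}

#' @export
print.gsd4_score_matrix <- function(x, ...) {
  cat(sprintf("<gsd4_score_matrix: %d scored, %d unscorable>\n",
              x$n_scored, x$n_unscored))
  wide <- tidyr::pivot_wider(x$counts, names_from = "h_score",
                             values_from = "count")
  print(wide)
  invisible(x)
}

#' @export
tidy.gsd4_score_matrix <- function(x, ...) {
  mutate(x$counts,
         score = paste0(.data$n_score, "-", .data$h_score),
         subtype = classify_subtype(.data$n_score, .data$h_score))
}

#' Fraction of scored patients consistent with an established subtype
#'
#' The established subtypes correspond exactly to the score combinations
#' N3-H0, N1-H0, N0-H3, and N0-H1; every other complete combination is not
#' fully consistent with any of them.
#'
#' @param x A `gsd4_score_matrix` (or a cohort, which is scored first).
#' @return A tibble with `n_consistent`, `n_scored`, `fraction`, `percent`.
#' @export
subtype_consistency <- function(x) {
  if (!inherits(x, "gsd4_score_matrix")) x <- score_matrix(x)
  if (x$n_scored == 0) {
    abort("subtype consistency is undefined for a cohort with no scored patients")
  }
  established <- tidy(x) %>%
    filter(.data$score %in% c("N3-H0", "N1-H0", "N0-H3", "N0-H1"))
  n_con <- sum(established$count)
  tibble(n_consistent = n_con, n_scored = x$n_scored,
         fraction = n_con / x$n_scored,
         percent = .pct(n_con, x$n_scored))
}

#' Summarize tri-system involvement as Venn categories
#'
#' Counts patients over the eight Venn regions among those whose hepatic,
#' neuromuscular, and cardiac statuses are all determinable; the rest are
#' tallied as `not_assessable`. Prenatal deaths are excluded.
#'
#' @param cohort A cohort tibble, or an involvement table from
#'   [assess_involvement()].
#' @return A `gsd4_venn_summary`: list with `counts` (tibble `category`,
#'   `count` over the 8 assessable categories), `n_assessable`, and
#'   `n_not_assessable`.
#' @export
venn_summary <- function(cohort) {
  inv <- if (is.data.frame(cohort) && "venn" %in% names(cohort)) {
    as_tibble(cohort)
  } else {
    assess_involvement(cohort)
  }
  assessable <- filter(inv, .data$venn != "not_assessable")
  counts <- tibble(category = setdiff(.venn_levels, "not_assessable")) %>%
    left_join(count(assessable, category = .data$venn, name = "count"),
              by = "category") %>%
    mutate(count = if_else(is.na(.data$count), 0L, as.integer(.data$count)))
  structure(
    list(counts = counts,
         n_assessable = nrow(assessable),
         n_not_assessable = nrow(inv) - nrow(assessable)),
    class = "gsd4_venn_summary"
  )
}

#' @export
print.gsd4_venn_summary <- function(x, ...) {
  cat(sprintf("<gsd4_venn_summary: %d tri-assessable, %d not assessable>\n",
              x$n_assessable, x$n_not_assessable))
  print(mutate(x$counts, percent = .pct(.data$count, x$n_assessable)))
  invisible(x)
}

#' Per-system involvement prevalence
#'
#' Prevalence of involvement per system among patients whose status for that
#' system is determinable (present or absent). Prenatal deaths are excluded.
#' A system with no assessable patients gets an `NA` fraction (flagged, never
#' silently zero).
#'
#' @param cohort A cohort tibble, or an involvement table from
#'   [assess_involvement()].
#' @param system Systems to tabulate; defaults to all three.
#' @return A tibble with columns `system`, `n_assessable`, `n_present`,
#'   `fraction`, `percent`.
#' @export
involvement_prevalence <- function(cohort,
                                   system = c("hepatic", "neuromuscular",
                                              "cardiac")) {
  system <- match.arg(system, several.ok = TRUE)
  inv <- if (is.data.frame(cohort) && all(system %in% names(cohort))) {
    as_tibble(cohort)
  } else {
    assess_involvement(cohort)
  }
  bind_rows(map(system, function(sys) {
    st <- inv[[sys]]
    n_assessable <- sum(st != "unknown")
    n_present <- sum(st == "present")
    tibble(system = sys, n_assessable = n_assessable, n_present = n_present,
           fraction = if (n_assessable > 0) n_present / n_assessable else NA_real_,
           percent = .pct(n_present, n_assessable))
  }))
}

# Death-timing bins (ages in months). `death_bins` partitions [0, Inf):
# <6 months, 6 months to <4 years, >=4 years. `cluster_bins` reproduces the
# death-timing clusters conventionally reported for this disorder — 0-4
# months, 6 months-3 years, >4 years — which leave gaps; deaths falling in a
# gap land in `other` rather than being widened into a neighboring cluster.
.bin_death_months <- function(age) {
  case_when(
    age < 6 ~ "lt_6mo",
    age < 48 ~ "mo6_to_lt4y",
    TRUE ~ "ge_4y"
  )
}

.cluster_death_months <- function(age) {
  case_when(
    age <= 4 ~ "mo0_to_4",
    age >= 6 & age <= 36 ~ "mo6_to_y3",
    age > 48 ~ "gt_y4",
    TRUE ~ "other"
  )
}

#' Summarize vital status and death timing
#'
#' Tallies alive/deceased among patients with known vital status and bins
#' deaths by age: prenatal deaths form their own bin; postnatal deaths are
#' binned half-open on months both as a partition (`death_bins`: <6 months,
#' 6 months to <4 years, >=4 years) and as the conventionally reported
#' death-timing clusters (`cluster_bins`: 0-4 months, 6 months-3 years,
#' >4 years, with gap ages in `other`). A death at an unknown age is surfaced
#' in `n_death_age_unknown`, never silently dropped.
#'
#' @param cohort A cohort tibble (prenatal deaths included; they are counted
#'   in the prenatal bin).
#' @return A `gsd4_survival_summary`: list with `n_known_status`, `n_alive`,
#'   `n_deceased`, `n_death_age_unknown`, `death_bins` and `cluster_bins`
#'   tibbles (`bin`, `count`, `percent_of_deaths`).
#' @export
survival_summary <- function(cohort) {
  cohort <- as_cohort(cohort)
  known <- filter(cohort, .data$vital_status != "unknown")
  deceased <- filter(known, .data$vital_status == "deceased")
  postnatal <- filter(deceased, !.data$prenatal_death)
  aged <- filter(postnatal, !is.na(.data$age_at_death_months))
  n_deceased <- nrow(deceased)
  n_unknown_age <- nrow(postnatal) - nrow(aged)

  tab <- function(levels, assign) {
    tibble(bin = levels) %>%
      left_join(count(tibble(bin = assign), .data$bin, name = "count"),
                by = "bin") %>%
      mutate(count = if_else(is.na(.data$count), 0L, as.integer(.data$count)),
             percent_of_deaths = .pct(.data$count, n_deceased))
  }
  death_bins <- tab(c("prenatal", "lt_6mo", "mo6_to_lt4y", "ge_4y"),
                    c(rep("prenatal", sum(deceased$prenatal_death)),
                      .bin_death_months(aged$age_at_death_months)))
  cluster_bins <- tab(c("prenatal", "mo0_to_4", "mo6_to_y3", "gt_y4", "other"),
                      c(rep("prenatal", sum(deceased$prenatal_death)),
                        .cluster_death_months(aged$age_at_death_months)))
  structure(
    list(n_known_status = nrow(known),
         n_alive = sum(known$vital_status == "alive"),
         n_deceased = n_deceased,
         n_death_age_unknown = n_unknown_age,
         percent_deceased = .pct(n_deceased, nrow(known)),
         percent_alive = .pct(sum(known$vital_status == "alive"), nrow(known)),
         death_bins = death_bins,
         cluster_bins = cluster_bins),
    class = "gsd4_survival_summary"
  )
}

#' @export
print.gsd4_survival_summary <- function(x, ...) {
  cat(sprintf(
    "<gsd4_survival_summary: %d known status; %d alive (%.1f%%), %d deceased (%.1f%%)>\n",
    x$n_known_status, x$n_alive, x$percent_alive, x$n_deceased,
    x$percent_deceased))
  if (x$n_death_age_unknown > 0) {
    cat(sprintf("  deaths at unknown age: %d\n", x$n_death_age_unknown))
  }
  print(x$cluster_bins)
  invisible(x)
}
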