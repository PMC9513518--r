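small_cohort <- function() {
  dplyr::bind_rows(
    # N3-H0, tri-assessable (cardiac absent)
    patient_record("A", findings("hypotonia"),
                   neuromuscular_onset = "at_birth",
                   vital_status = "deceased", age_at_death_months = 2,
                   explicit_normal_hepatic = TRUE,
                   explicit_normal_cardiac = TRUE),
    # N0-H1, cardiac unknown
    patient_record("B", findings("hepatomegaly"), vital_status = "alive",
                   age_at_last_followup_months = 30,
                   explicit_normal_neuromuscular = TRUE),
    # unscorable: onset unreported
    patient_record("C", findings(c("hypotonia", "hepatomegaly")),
                   vital_status = "alive", age_at_last_followup_months = 50),
    # prenatal death: excluded everywhere except the death bins
    patient_record("D", prenatal_death = TRUE, vital_status = "deceased")
  )
}

test_that("score_matrix excludes prenatal deaths and tallies incompleteness", {
  sm <- score_matrix(small_cohort())
  expect_equal(sm$n_scored, 2)
  expect_equal(sm$n_unscored, 1)
  expect_equal(sum(sm$counts$count), sm$n_scored)
  grab <- function(n, h) {
    sm$counts$count[sm$counts$n_score == n & sm$counts$h_score == h]
  }
  expect_equal(grab("N3", "H0"), 1L)
  expect_equal(grab("N0", "H1"), 1L)

  empty <- score_matrix(as_cohort(tibble::tibble(patient_id = character())))
  expect_equal(empty$n_scored, 0)
  expect_true(all(empty$counts$count == 0))
})

test_that("subtype consistency is the mass in the four established cells", {
  sm <- score_matrix(small_cohort())
  sc <- subtype_consistency(sm)
  expect_equal(sc$n_consistent, 2)
  expect_equal(sc$fraction, 1)

  one_cell <- function(n, h) {
    counts <- tidyr::expand_grid(n_score = paste0("N", 0:3),
                                 h_score = paste0("H", 0:3)) |>
      dplyr::mutate(count = ifelse(n_score == n & h_score == h, 5L, 0L))
    structure(list(counts = counts, n_scored = 5L, n_unscored = 0L),
              class = "gsd4_score_matrix")
  }
  expect_equal(subtype_consistency(one_cell("N0", "H1"))$fraction, 1)
  expect_equal(subtype_consistency(one_cell("N2", "H2"))$fraction, 0)
  empty <- structure(list(counts = one_cell("N0", "H0")$counts,
                          n_scored = 0L, n_unscored = 0L),
                     class = "gsd4_score_matrix")
  expect_error(subtype_consistency(empty), "undefined")
})

test_that("venn_summary separates tri-assessable patients", {
  vs <- venn_summary(small_cohort())
  expect_equal(vs$n_assessable, 1)
  expect_equal(vs$n_not_assessable, 2)
  expect_equal(sum(vs$counts$count), vs$n_assessable)
  expect_equal(
    vs$counts$count[vs$counts$category == "neuromuscular_only"], 1L)
})

test_that("involvement_prevalence uses assessable denominators and flags empty ones", {
  prev <- involvement_prevalence(small_cohort())
  hep <- prev[prev$system == "hepatic", ]
  expect_equal(hep$n_assessable, 3)
  expect_equal(hep$n_present, 2)
  nothing <- as_cohort(tibble::tibble(patient_id = "Z",
                                      vital_status = "alive"))
  p0 <- involvement_prevalence(nothing)
  expect_true(all(p0$n_assessable == 0))
  expect_true(all(is.na(p0$fraction)))
})

test_that("survival_summary bins deaths with strict boundaries", {
  coh <- dplyr::bind_rows(
    patient_record("P1", prenatal_death = TRUE, vital_status = "deceased"),
    patient_record("P2", vital_status = "deceased", age_at_death_months = 3),
    patient_record("P3", vital_status = "deceased", age_at_death_months = 5),
    patient_record("P4", vital_status = "deceased", age_at_death_months = 24),
    patient_record("P5", vital_status = "deceased", age_at_death_months = 48),
    patient_record("P6", vital_status = "deceased", age_at_death_months = 100),
    patient_record("P7", vital_status = "deceased"),
    patient_record("P8", vital_status = "alive"),
    patient_record("P9", vital_status = "unknown")
  )
  sv <- survival_summary(coh)
  expect_equal(sv$n_known_status, 8)
  expect_equal(sv$n_deceased, 7)
  expect_equal(sv$n_death_age_unknown, 1)
  bins <- function(tab, bin) tab$count[tab$bin == bin]
  # death at exactly 4 years lands in the >=4y partition bin
  expect_equal(bins(sv$death_bins, "ge_4y"), 2L)
  expect_equal(bins(sv$death_bins, "lt_6mo"), 2L)
  expect_equal(bins(sv$death_bins, "mo6_to_lt4y"), 1L)
  # the reported clusters leave gaps: 5 months and exactly 48 months fall in
  # "other" rather than widening a cluster
  expect_equal(bins(sv$cluster_bins, "other"), 2L)
  expect_equal(bins(sv$cluster_bins, "mo0_to_4"), 1L)
  expect_equal(bins(sv$cluster_bins, "gt_y4"), 1L)

  alive <- patient_record("A", vital_status = "alive")
  expect_true(all(survival_summary(alive)$death_bins$count == 0))
})

test_that("every non-prenatal patient is conserved across the partitions", {
  coh <- reference_cohort()
  n_postnatal <- sum(!coh$prenatal_death)
  sm <- score_matrix(coh)
  expect_equal(sm$n_scored + sm$n_unscored, n_postnatal)
  vs <- venn_summary(coh)
  expect_equal(vs$n_assessable + vs$n_not_assessable, n_postnatal)
})

test_that("report percentages recompute from counts with half-up rounding", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(24.35, 1), 24.4)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  report <- build_report(reference_cohort())
  td <- tidy(report)
  with_den <- td[!is.na(td$denominator) & td$denominator > 0, ]
  expect_equal(with_den$fraction, with_den$count / with_den$denominator)
  gl <- glance(report)
  expect_equal(gl$pct_established_subtype,
               round_half_up(100 * report$subtype_consistency$fraction, 1))
})

test_that("reports round-trip through JSON and render to markdown", {
  report <- build_report(small_cohort())
  path <- withr::local_tempfile(fileext = ".json")
  report_to_json(report, path)
  back <- report_from_json(path)
  expect_equal(back, report, ignore_attr = FALSE)

  md <- report_markdown(report)
  expect_match(md, "Score matrix")
  expect_match(md, "\\| category \\| n \\| % \\|")

  empty <- build_report(as_cohort(tibble::tibble(patient_id = character())))
  expect_true(is.na(empty$subtype_consistency$percent))
  expect_match(report_markdown(empty), "0 patients|patients: 0")
})

test_that("plot helpers return ggplot objects", {
  report <- build_report(small_cohort())
  expect_s3_class(plot_score_matrix(report), "ggplot")
  expect_s3_class(plot_involvement(report), "ggplot")
  expect_s3_class(plot_survival(report), "ggplot")
  expect_s3_class(ggplot2::autoplot(report), "ggplot")
})
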