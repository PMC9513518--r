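nm_rec <- function(onset, vital = "alive", death = NA_real_, fu = NA_real_,
                   fnd = findings("hypotonia")) {
  patient_record("X", fnd, neuromuscular_onset = onset, vital_status = vital,
                 age_at_death_months = death,
                 age_at_last_followup_months = fu,
                 explicit_normal_hepatic = TRUE)
}

hep_rec <- function(fnd, vital = "alive", death = NA_real_, fu = NA_real_,
                    lt = "unknown", tx = NA_real_, attr = NA) {
  patient_record("X", fnd, vital_status = vital, age_at_death_months = death,
                 age_at_last_followup_months = fu, liver_transplant = lt,
                 age_at_transplant_months = tx,
                 explicit_normal_neuromuscular = TRUE,
                 death_attributed_hepatic = attr)
}

test_that("severe hepatic features follow the feature list and the platelet threshold", {
  expect_true(has_severe_hepatic_features(
    hep_rec(findings("splenomegaly", platelet_count = 120000))))
  # boundary: the threshold is strict at 150,000/µl
  expect_false(has_severe_hepatic_features(
    hep_rec(findings("splenomegaly", platelet_count = 200000))))
  expect_false(has_severe_hepatic_features(
    hep_rec(findings("splenomegaly", platelet_count = 150000))))
  expect_true(has_severe_hepatic_features(
    hep_rec(findings("splenomegaly", platelet_count = 149999))))
  # splenomegaly without a documented low platelet count is not severe
  expect_false(has_severe_hepatic_features(hep_rec(findings("splenomegaly"))))
  expect_false(has_severe_hepatic_features(
    hep_rec(findings(c("hepatomegaly", "elevated_alt")))))
  expect_true(has_severe_hepatic_features(hep_rec(findings("liver_failure"))))
  expect_true(has_severe_hepatic_features(hep_rec(findings("gi_bleed"))))
  # the newborn-period / heart-failure exclusions apply to severity too
  expect_false(has_severe_hepatic_features(
    hep_rec(findings("hyperbilirubinemia", newborn_period_only = TRUE))))
  expect_true(has_severe_hepatic_features(
    hep_rec(findings("hyperbilirubinemia"))))
  expect_false(has_severe_hepatic_features(
    hep_rec(findings("ascites", heart_failure_context_only = TRUE))))
})

test_that("neuromuscular scoring separates onset timing and survival", {
  expect_equal(score_neuromuscular(nm_rec("at_birth", "deceased", death = 2)),
               "N3")
  expect_equal(score_neuromuscular(nm_rec("prenatal", "deceased", death = 5.9)),
               "N3")
  # survival to the 6-month cutoff takes the milder class
  expect_equal(score_neuromuscular(nm_rec("at_birth", "deceased", death = 6)),
               "N2")
  expect_equal(score_neuromuscular(nm_rec("at_birth", fu = 120)), "N2")
  expect_equal(score_neuromuscular(nm_rec("postnatal")), "N1")
  # censored before the cutoff: refuse to guess
  expect_equal(score_neuromuscular(nm_rec("at_birth", fu = 4)), "unscorable")
  expect_equal(score_neuromuscular(nm_rec("unknown", fu = 120)), "unscorable")
  expect_equal(score_neuromuscular(
    nm_rec("none_reported", fnd = findings(),
           fu = 12) |> dplyr::mutate(explicit_normal_neuromuscular = TRUE)),
    "N0")
})

test_that("hepatic scoring combines severity with the 5-year transplant/death cutoff", {
  severe <- findings(c("liver_failure", "hepatomegaly"))
  expect_equal(score_hepatic(hep_rec(severe, lt = "yes", tx = 18, fu = 40)),
               "H3")
  expect_equal(score_hepatic(hep_rec(severe, "deceased", death = 30)), "H3")
  # survived past 5 years without transplant, later severe course: H2
  expect_equal(score_hepatic(hep_rec(severe, "deceased", death = 156)), "H2")
  expect_equal(score_hepatic(hep_rec(severe, fu = 100)), "H2")
  # transplant at or after 5 years is still H2
  expect_equal(score_hepatic(hep_rec(severe, lt = "yes", tx = 80, fu = 90)),
               "H2")
  expect_equal(score_hepatic(hep_rec(severe, "deceased", death = 60)), "H2")
  # alive under 5 years without transplant: censored
  expect_equal(score_hepatic(hep_rec(severe, fu = 30)), "unscorable")
  expect_equal(score_hepatic(
    hep_rec(findings(c("hepatomegaly", "elevated_alt")), fu = 96)), "H1")
  expect_equal(score_hepatic(
    patient_record("X", explicit_normal_hepatic = TRUE,
                   vital_status = "alive")), "H0")
})

test_that("hepatic death attribution is optional and off by default", {
  severe <- findings("liver_failure")
  unattributed <- hep_rec(severe, "deceased", death = 30, attr = FALSE)
  expect_equal(score_hepatic(unattributed), "H3")
  expect_equal(score_hepatic(unattributed,
                             require_hepatic_death_attribution = TRUE),
               "unscorable")
  attributed <- hep_rec(severe, "deceased", death = 30, attr = TRUE)
  expect_equal(score_hepatic(attributed,
                             require_hepatic_death_attribution = TRUE), "H3")
})

test_that("classify_subtype matches the decision table on all 25 combinations", {
  grid <- expand.grid(n = c("N0", "N1", "N2", "N3", "unscorable"),
                      h = c("H0", "H1", "H2", "H3", "unscorable"),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 25)
  got <- classify_subtype(grid$n, grid$h)
  want <- mapply(oracle_subtype, grid$n, grid$h, USE.NAMES = FALSE)
  expect_equal(got, want)
  # the four established subtypes are exactly these combinations
  established <- grid[got %in% c("perinatal_congenital_neuromuscular",
                                 "juvenile_neuromuscular", "classic_hepatic",
                                 "non_progressive_hepatic"), ]
  expect_setequal(paste0(established$n, "-", established$h),
                  c("N3-H0", "N1-H0", "N0-H3", "N0-H1"))
})

test_that("score_phenotype composes assessment and both scales", {
  neonate <- patient_record(
    "L1", findings(c("hypotonia", "ventilator_dependent_respiratory_weakness")),
    neuromuscular_onset = "at_birth", vital_status = "deceased",
    age_at_death_months = 1, explicit_normal_hepatic = TRUE)
  s <- score_phenotype(neonate)
  expect_equal(s$score, "N3-H0")
  expect_equal(s$subtype, "perinatal_congenital_neuromuscular")

  mixed <- patient_record(
    "L2", findings(c("hypotonia", "hepatomegaly", "jaundice")),
    neuromuscular_onset = "at_birth", vital_status = "deceased",
    age_at_death_months = 20, liver_transplant = "yes",
    age_at_transplant_months = 18)
  s2 <- score_phenotype(mixed)
  expect_equal(s2$score, "N2-H3")
  expect_equal(s2$subtype, "mixed")

  cardiac_only <- patient_record(
    "L3", findings("cardiomyopathy"), vital_status = "alive",
    explicit_normal_hepatic = TRUE, explicit_normal_neuromuscular = TRUE)
  s3 <- score_phenotype(cardiac_only)
  expect_equal(s3$score, "N0-H0")
  expect_equal(s3$subtype, "no_hepatic_no_neuromuscular")

  incomplete <- patient_record("L4", findings("hypotonia"),
                               neuromuscular_onset = "unknown",
                               vital_status = "alive")
  s4 <- score_phenotype(incomplete)
  expect_false(s4$complete)
  expect_equal(s4$subtype, "unclassifiable")
})

test_that("scoring agrees with the independent decision-table oracle on randomized records", {
  withr::with_seed(2024, {
    coh <- random_cohort(2000)
  })
  scores <- score_phenotype(coh)
  want_n <- vapply(seq_len(nrow(coh)),
                   function(i) oracle_n_score(coh[i, ]), character(1))
  want_h <- vapply(seq_len(nrow(coh)),
                   function(i) oracle_h_score(coh[i, ]), character(1))
  expect_equal(scores$n_score, want_n)
  expect_equal(scores$h_score, want_h)
  expect_equal(scores$subtype,
               mapply(oracle_subtype, want_n, want_h, USE.NAMES = FALSE))
})

test_that("severity is monotone under added severe features and shortened survival", {
  withr::with_seed(31, {
    coh <- random_cohort(150)
  })
  rank_h <- function(h) match(h, c("H0", "H1", "H2", "H3"))
  base <- score_phenotype(coh)
  worse <- coh
  worse$explicit_normal_hepatic <- FALSE
  worse$findings <- lapply(worse$findings, function(f) {
    dplyr::bind_rows(f, findings("liver_failure"))
  })
  after <- score_phenotype(worse)
  both <- !is.na(rank_h(base$h_score)) & !is.na(rank_h(after$h_score))
  expect_true(all(rank_h(after$h_score)[both] >= rank_h(base$h_score)[both]))

  # shortening survival below a cutoff never softens the class
  early <- nm_rec("at_birth", "deceased", death = 2)
  late <- nm_rec("at_birth", "deceased", death = 10)
  expect_equal(score_neuromuscular(early), "N3")
  expect_equal(score_neuromuscular(late), "N2")
})
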