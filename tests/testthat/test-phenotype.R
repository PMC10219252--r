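test_that("ICD-10 expansion: exact first, then longest prefix, unknown warns", {
  tab <- default_icd10_table()
  expect_identical(expand_icd10("E75.2", tab),
                   "Sphingolipidosis including Fabry disease")
  expect_identical(expand_icd10("I42.1", tab),
                   "Obstructive hypertrophic cardiomyopathy")
  # prefix fallback: I42.7 is not listed, falls back to I42
  expect_identical(expand_icd10("I42.7", tab), "Cardiomyopathy")
  expect_warning(d <- expand_icd10("Z99.9", c(A00 = "x")), "unknown")
  expect_identical(d, "")
  expect_error(expand_icd10("not-a-code", tab), "malformed")
  expect_error(expand_icd10("I4", tab), "malformed")
})

test_that("lab rules fire on their comparator with strict boundaries", {
  rules <- default_catalog()$lab_rules
  f <- parse_labs(list(list(analyte = "egfr", value = 25,
                            unit = "mL/min/1.73m2")), rules)
  expect_identical(f$finding, "reduced_egfr")
  expect_equal(nrow(parse_labs(list(), rules)), 0)
  # value exactly at the threshold of a strict "<" rule: no finding
  at <- parse_labs(list(list(analyte = "egfr", value = 60,
                             unit = "mL/min/1.73m2")), rules)
  expect_equal(nrow(at), 0)
  expect_warning(
    mm <- parse_labs(list(list(analyte = "egfr", value = 25, unit = "mol/L")),
                     rules),
    "unit mismatch")
  expect_equal(nrow(mm), 0)
})

test_that("cohort filter applies age bounds and exclusion conditions", {
  cat13 <- default_catalog()
  mk <- function(age, codes = list()) list(patient_id = "p", age = age,
                                           icd10_codes = codes)
  expect_true(cohort_filter(mk(45), cat13)$eligible)
  expect_true(cohort_filter(mk(18), cat13)$eligible)
  expect_true(cohort_filter(mk(75), cat13)$eligible)
  expect_identical(cohort_filter(mk(17), cat13)$reason, "age")
  expect_identical(cohort_filter(mk(76), cat13)$reason, "age")
  expect_identical(cohort_filter(mk(50, list("Z51.1")), cat13)$reason,
                   "chemotherapy")
  # affirmed mention of an exclusion condition also disqualifies
  lex <- default_lexicon()
  ents <- extract_entities("Patient under palliative care.", lex)
  expect_identical(cohort_filter(mk(50), cat13, ents)$reason, "palliative_care")
  # a negated mention does not
  ents2 <- extract_entities("Patient not under palliative care.", lex)
  expect_true(cohort_filter(mk(50), cat13, ents2)$eligible)
})

test_that("feature assignment maps each evidence channel and ignores negation", {
  cat13 <- default_catalog()
  lex <- default_lexicon()
  ents <- extract_entities("Examination revealed angiokeratoma.", lex)
  a <- assign_features(ents, catalog = cat13)
  expect_true("angiokeratoma" %in% names(a$present))
  expect_match(a$present$angiokeratoma, "term:angiokeratoma")

  neg <- extract_entities("No stroke.", lex)
  a2 <- assign_features(neg, catalog = cat13)
  expect_false("stroke" %in% names(a2$present))

  a3 <- assign_features(NULL, icd_codes = "I42.1", catalog = cat13)
  expect_true("hypertrophic_cardiomyopathy" %in% names(a3$present))
  expect_match(a3$present$hypertrophic_cardiomyopathy, "icd10:I42.1")

  labf <- parse_labs(list(list(analyte = "egfr", value = 30,
                               unit = "mL/min/1.73m2")), cat13$lab_rules)
  a4 <- assign_features(NULL, lab_findings = labf, catalog = cat13)
  expect_true("renal_failure" %in% names(a4$present))
})

test_that("assignment is monotone in affirmed evidence", {
  cat13 <- default_catalog()
  lex <- default_lexicon()
  base <- extract_entities("Examination revealed proteinuria.", lex)
  more <- extract_entities(
    "Examination revealed proteinuria. Patient reports stroke.", lex)
  a1 <- assign_features(base, catalog = cat13)
  a2 <- assign_features(more, catalog = cat13)
  expect_true(all(names(a1$present) %in% names(a2$present)))
})

test_that("confounders veto features idempotently and reversibly", {
  cat13 <- default_catalog()
  lex <- default_lexicon()
  rec <- list(patient_id = "p", age = 50, icd10_codes = list())
  with_conf <- extract_entities(
    "Documented finding of renal failure. Known history of amyloidosis.", lex)
  a <- assign_features(with_conf, catalog = cat13)
  expect_true("renal_failure" %in% names(a$present))
  v <- apply_exclusions(a, rec, cat13, with_conf)
  expect_false("renal_failure" %in% names(v$present))
  expect_identical(v$vetoed$renal_failure, "amyloidosis")
  # idempotent
  expect_identical(apply_exclusions(v, rec, cat13, with_conf), v)

  # PFO vetoes stroke
  pfo <- extract_entities("History of stroke. Patent foramen ovale noted.", lex)
  vs <- apply_exclusions(assign_features(pfo, catalog = cat13), rec, cat13, pfo)
  expect_false("stroke" %in% names(vs$present))
  expect_identical(vs$vetoed$stroke, "patent_foramen_ovale")

  # removing the confounder restores the feature, changing nothing else
  without <- extract_entities("Documented finding of renal failure.", lex)
  u <- apply_exclusions(assign_features(without, catalog = cat13), rec, cat13,
                        without)
  expect_true("renal_failure" %in% names(u$present))
  expect_length(u$vetoed, 0)
})

test_that("the default catalog has 13 features across the 5 sign groups", {
  cat13 <- default_catalog()
  expect_length(cat13$features, 13)
  groups <- vapply(cat13$features, function(f) f$sign_group, "")
  expect_setequal(unique(groups),
                  c("cardiovascular", "kidney", "skin", "neurological", "eye"))
  for (f in cat13$features) {
    expect_true(f$base_score >= 0 && f$base_score <= 3)
    if (!is.null(f$age_modifier)) expect_lte(f$age_modifier$score, 3)
  }
})
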