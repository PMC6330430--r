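test_that("decade ages impute to the intake convention", {
  expect_identical(impute_age(age_record("EARLY_DECADE", 70)), 72L)
  expect_identical(impute_age(age_record("LATE_DECADE", 70)), 78L)
  expect_identical(impute_age(age_record("DECADE", 70)), 75L)
  expect_identical(impute_age(age_record("EXACT", 44)), 44L)
  expect_identical(impute_age(44), 44L)
})

test_that("imputation is idempotent on exact ages and stays in the decade", {
  for (decade in seq(20L, 90L, 10L)) {
    for (kind in c("EARLY_DECADE", "LATE_DECADE", "DECADE")) {
      v <- impute_age(age_record(kind, decade))
      expect_gte(v, decade)
      expect_lt(v, decade + 10L)
      expect_identical(impute_age(age_record("EXACT", v)), v)
    }
  }
  # configurable offsets
  expect_identical(
    impute_age(age_record("DECADE", 40),
               offsets = c(EARLY_DECADE = 1L, LATE_DECADE = 9L, DECADE = 4L)),
    44L)
})

test_that("unknown ages are routed to any-age clauses, never imputed", {
  expect_error(impute_age(age_record("UNKNOWN")), "any age")
  expect_identical(impute_age(age_record("UNKNOWN"), strict = FALSE),
                   NA_integer_)
})

test_that("free-text cancer types normalize onto the vocabulary", {
  d <- normalize_cancer("Breast - DCIS", 52)
  expect_identical(d$cancer_type, "breast")
  expect_true("DCIS" %in% d$qualifiers)

  d2 <- normalize_cancer("prostate", age_record("DECADE", 60))
  expect_true("GLEASON_GT7" %in% d2$qualifiers)

  expect_identical(normalize_cancer("myxofibrosarcoma of the toe", 70)$cancer_type,
                   "other_unspecified")
  expect_identical(normalize_cancer("colon", 60)$cancer_type, "colorectal")
  expect_identical(normalize_cancer("Stomach", 60)$cancer_type, "gastric")
  d3 <- normalize_cancer("breast - triple negative", 45)
  expect_true("TRIPLE_NEGATIVE" %in% d3$qualifiers)
})

test_that("the vocabulary has 36 named types and round-trips canonically", {
  v <- cancer_vocabulary()
  expect_length(v$types, 36L)
  for (type in v$types) {
    expect_identical(normalize_cancer(gsub("_", " ", type), 50)$cancer_type,
                     type)
  }
  # extension hook
  v2 <- cancer_vocabulary(extra = c("GBM" = "cns_brain"))
  expect_identical(normalize_cancer("GBM", 50, vocabulary = v2)$cancer_type,
                   "cns_brain")
})

test_that("ovarian equivalents are ovarian, fallopian tube, peritoneal", {
  expect_true(all(is_ovarian_equivalent(
    c("ovarian", "fallopian_tube", "primary_peritoneal"))))
  expect_false(any(is_ovarian_equivalent(c("cervical", "endometrial",
                                           "breast"))))
})

test_that("the LS-related set matches the guideline list", {
  expect_true(all(is_ls_related(
    c("colorectal", "endometrial", "gastric", "ovarian", "pancreatic",
      "renal_pelvis_ureter", "cns_brain", "small_intestine",
      "sebaceous_adenoma", "sebaceous_carcinoma", "keratoacanthoma"))))
  expect_false(any(is_ls_related(c("lung", "breast", "melanoma", "renal"))))
  # the Amsterdam II set is strictly narrower
  expect_true(all(is_amsterdam_cancer(
    c("colorectal", "endometrial", "small_intestine", "renal_pelvis_ureter"))))
  expect_false(any(is_amsterdam_cancer(c("gastric", "ovarian", "cns_brain"))))
})

test_that("pedigree normalization applies the prostate assumption", {
  p <- ped_with(fm("father", diagnosis("prostate", 70)))
  p <- normalize_pedigree(p)
  expect_true("GLEASON_GT7" %in% p$members[[1]]$diagnoses[[1]]$qualifiers)
  # idempotent
  expect_identical(normalize_pedigree(p), p)
})
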