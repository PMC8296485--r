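test_that("hypertension coding follows diagnosis+medication and pressure thresholds", {
  # (dx, meds, sbp, dbp) -> expected
  cases <- list(
    list(FALSE, FALSE, 140, 85, TRUE),   # SBP at inclusive threshold
    list(FALSE, FALSE, 120, 90, TRUE),   # DBP at inclusive threshold
    list(TRUE,  TRUE,  118, 72, TRUE),   # dx + meds, regardless of pressure
    list(TRUE,  FALSE, 118, 72, FALSE),  # dx without meds -> measured pressure
    list(FALSE, FALSE, 139, 89, FALSE))  # both strictly below
  for (cs in cases) {
    expect_identical(classify_hypertension(cs[[1]], cs[[2]], cs[[3]], cs[[4]]),
                     cs[[5]])
  }
  expect_error(classify_hypertension(FALSE, FALSE, 0, 80), "strictly positive")
  expect_error(classify_hypertension(FALSE, FALSE, 120, -5), "strictly positive")
})

test_that("diabetes coding: medication, fasting and 2-h thresholds; missing 2-h", {
  expect_true(classify_diabetes(7.0, NA, FALSE))     # inclusive at 7.0
  expect_true(classify_diabetes(5.2, 11.1, FALSE))   # inclusive at 11.1
  expect_true(classify_diabetes(5.2, NA, TRUE))      # medication alone
  expect_false(classify_diabetes(5.2, 7.8, FALSE))
  expect_false(classify_diabetes(6.9, NA, FALSE))    # absent 2-h cannot force positivity
  expect_error(classify_diabetes(-1, NA, FALSE), "strictly positive")
})

test_that("dyslipidemia and obesity thresholds are inclusive in the printed direction", {
  expect_true(classify_dyslipidemia(6.22, 1.0, 1.5, FALSE))
  expect_true(classify_dyslipidemia(5.0, 2.26, 1.5, FALSE))
  expect_true(classify_dyslipidemia(5.0, 1.0, 1.03, FALSE))   # HDL strictly below 1.04
  expect_false(classify_dyslipidemia(5.0, 1.0, 1.04, FALSE))  # boundary HDL is normal
  expect_true(classify_dyslipidemia(5.0, 1.0, 1.5, TRUE))     # on lipid drugs

  expect_true(classify_obesity(1.70, 1.70^2 * 28))  # BMI exactly 28
  expect_false(classify_obesity(1.70, 70))          # BMI 24.22
  expect_true(classify_obesity(1.60, 72))           # BMI 28.125
  expect_error(classify_obesity(0, 70), "strictly positive")
})

test_that("exercise and drinking levels", {
  expect_identical(classify_exercise(3, 30, FALSE), "sufficient")
  expect_identical(classify_exercise(0, 0, TRUE), "sufficient")  # heavy labor
  expect_identical(classify_exercise(2, 60, FALSE), "lack")
  expect_identical(classify_exercise(5, 20, FALSE), "lack")

  expect_identical(classify_drinking(TRUE, 3, 100), "frequent")
  expect_identical(classify_drinking(FALSE, 0, 0), "never")
  expect_identical(classify_drinking(TRUE, 2, 250), "occasional")
  expect_identical(classify_drinking(TRUE, 3, 99), "occasional")
})

test_that("classification is monotone in the harmful direction", {
  # raising sbp/fpg/tc/tg or lowering hdl never flips positive -> negative
  grid <- seq(0.5, 2, by = 0.25)
  for (mult in grid) {
    base <- classify_hypertension(FALSE, FALSE, 140, 60)
    expect_true(classify_hypertension(FALSE, FALSE, 140 * (1 + mult), 60) >= base)
    expect_true(classify_diabetes(7.0 * (1 + mult)) >= classify_diabetes(7.0))
    expect_true(classify_dyslipidemia(6.22 * (1 + mult), 1, 1.5) >=
                  classify_dyslipidemia(6.22, 1, 1.5))
    expect_true(classify_dyslipidemia(5, 1, 1.03 / (1 + mult)) >=
                  classify_dyslipidemia(5, 1, 1.03))
  }
})

test_that("derive_profiles applies every classifier, deterministically", {
  recs <- rbind(
    make_records(1, id = 1L, age_years = 62L),                     # only age
    make_records(1, id = 2L, age_years = 45L, dx_hypertension = TRUE,
                 on_antihypertensives = TRUE),                     # medication rule
    make_records(1, id = 3L, fpg_mmol_L = 7.4, smoker_6mo = TRUE,
                 exercise_sessions_per_week = 1L, cvd_case = TRUE))
  prof <- derive_profiles(recs)

  expect_identical(prof$age_ge_60, c(TRUE, FALSE, FALSE))
  expect_identical(prof$hypertension, c(FALSE, TRUE, FALSE))
  expect_identical(prof$diabetes, c(FALSE, FALSE, TRUE))
  expect_identical(prof$smoking, c(FALSE, FALSE, TRUE))
  expect_identical(prof$lack_of_exercise, c(FALSE, FALSE, TRUE))
  expect_identical(prof$cvd_case, c(FALSE, FALSE, TRUE))
  # row 1: only age_ge_60 among the six model factors
  expect_identical(sum(unlist(prof[1, model_factors()])), 1L)
  # idempotence / determinism: coding twice gives identical profiles
  expect_identical(prof, derive_profiles(recs))
})

test_that("record validation rejects under-age and malformed cohorts", {
  expect_error(derive_profiles(make_records(1, age_years = 39L)), "inclusion")
  bad <- make_records(2); bad$id <- c(1L, 1L)
  expect_error(derive_profiles(bad), "duplicate")
  expect_error(derive_profiles(make_records(1)[-3]), "missing columns")
  # classifier errors carry the record id context
  expect_error(derive_profiles(make_records(1, sbp_mmHg = -10)), "ids 1")
})

test_that("cohort and profile CSV round-trips preserve coding", {
  recs <- rbind(make_records(1, id = 1L, age_years = 70L, cvd_case = TRUE),
                make_records(1, id = 2L, pg2h_mmol_L = 12.0))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(recs, f)
  back <- read_cohort_csv(f)
  expect_identical(derive_profiles(back), derive_profiles(recs))
  # missing pg2h serialises as an empty cell
  expect_true(anyNA(utils::read.csv(f)$pg2h_mmol_L))

  prof <- derive_profiles(recs)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(prof, f2)
  prof2 <- read_profiles_csv(f2)
  expect_equal(prof2[model_factors()], prof[model_factors()])
  expect_identical(prof2$cvd_case, prof$cvd_case)
})
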