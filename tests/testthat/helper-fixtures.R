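# Fixture builders. Everything is generated in code; no stored data.

# A raw survey record for a healthy 45-year-old regular exerciser; override
# any field to create pathology.
make_records <- function(n = 1, ...) {
  rec <- data.frame(
    id = seq_len(n),
    sex = "female",
    age_years = 45L,
    sbp_mmHg = 118, dbp_mmHg = 72,
    height_m = 1.65, weight_kg = 60,
    fpg_mmol_L = 5.1, pg2h_mmol_L = NA_real_,
    tc_mmol_L = 4.5, tg_mmol_L = 1.2, hdl_mmol_L = 1.4,
    smoker_6mo = FALSE,
    drink_frequency = "never",
    exercise_sessions_per_week = 4L,
    exercise_minutes_per_session = 40,
    heavy_physical_labor = FALSE,
    dx_hypertension = FALSE, on_antihypertensives = FALSE,
    on_lipid_drugs = FALSE, on_glucose_drugs_or_insulin = FALSE,
    family_history_cvd = FALSE, cardiopathy = FALSE,
    cvd_case = FALSE,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (k in names(over)) rec[[k]] <- over[[k]]
  rec
}

# Coded-profile data.frame built directly (bypassing the raw-record layer).
make_profiles <- function(n, seed = 1, case_rate = 0.2) {
  set.seed(seed)
  df <- data.frame(id = seq_len(n))
  for (f in c(cvdrisk::model_factors(), "male", "alcohol", "obesity",
              "dyslipidemia", "cardiopathy")) {
    df[[f]] <- stats::runif(n) < 0.3
  }
  df$sex <- ifelse(df$male, "male", "female")
  df$cvd_case <- stats::runif(n) < case_rate
  # guarantee both outcome classes
  df$cvd_case[1] <- TRUE
  df$cvd_case[2] <- FALSE
  df
}

expect_equal_num <- function(object, expected, tol = 1e-12) {
  expect_equal(object, expected, tolerance = tol)
}
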