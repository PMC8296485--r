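# Diagnostic coding of raw survey records into binary risk factors.
#
# All classifiers are pure, vectorised functions of their arguments. The
# thresholds implement the study criteria exactly as printed, with the
# inclusivity direction stated for each (>= on the harmful side, strict <
# for low HDL). Units are fixed: pressures in mmHg, glucose and lipids in
# mmol/L, height in metres, weight in kg.

#' Classify hypertension
#'
#' A participant counts as hypertensive if they report a prior clinical
#' diagnosis *and* are currently on antihypertensive medication (regardless
#' of measured pressure), or otherwise if the measured pressure reaches
#' SBP >= 140 mmHg and/or DBP >= 90 mmHg. Diagnosed participants not on
#' medication are coded from the measured pressure.
#'
#' @param dx logical, prior clinician diagnosis of hypertension.
#' @param on_meds logical, currently taking antihypertensive drugs.
#' @param sbp,dbp measured systolic / diastolic pressure in mmHg; must be
#'   strictly positive.
#' @return logical vector.
#' @export
#' @examples
#' classify_hypertension(FALSE, FALSE, 140, 85)  # TRUE: SBP at threshold
#' classify_hypertension(TRUE, TRUE, 118, 72)    # TRUE: dx + medication
classify_hypertension <- function(dx, on_meds, sbp, dbp) {
  if (any(!is.finite(sbp)) || any(!is.finite(dbp)) ||
      any(sbp <= 0) || any(dbp <= 0)) {
    stop("invalid record: blood pressures must be finite and strictly positive",
         call. = FALSE)
  }
  ifelse(dx & on_meds, TRUE, sbp >= 140 | dbp >= 90)
}

#' Classify diabetes
#'
#' Positive on current glucose-lowering medication (or insulin), fasting
#' plasma glucose >= 7.0 mmol/L, or 2-h postprandial glucose >= 11.1 mmol/L.
#' A missing 2-h value means "not measured": the criterion is a disjunction,
#' so the remaining disjuncts decide.
#'
#' @param fpg fasting plasma glucose, mmol/L, strictly positive.
#' @param pg2h 2-h postprandial glucose, mmol/L, or `NA` when not measured.
#' @param on_meds logical, on hypoglycemic agents or insulin.
#' @return logical vector.
#' @export
classify_diabetes <- function(fpg, pg2h = NA_real_, on_meds = FALSE) {
  if (any(!is.finite(fpg)) || any(fpg <= 0)) {
    stop("invalid record: fasting glucose must be finite and strictly positive",
         call. = FALSE)
  }
  if (any(!is.na(pg2h) & pg2h <= 0)) {
    stop("invalid record: 2-h glucose, when present, must be strictly positive",
         call. = FALSE)
  }
  on_meds | fpg >= 7.0 | (!is.na(pg2h) & pg2h >= 11.1)
}

#' Classify dyslipidemia
#'
#' Positive on lipid-lowering medication, total cholesterol >= 6.22 mmol/L,
#' triglycerides >= 2.26 mmol/L, or HDL < 1.04 mmol/L.
#'
#' @param tc,tg,hdl total cholesterol, triglycerides, HDL in mmol/L.
#' @param on_lipid_drugs logical.
#' @return logical vector.
#' @export
classify_dyslipidemia <- function(tc, tg, hdl, on_lipid_drugs = FALSE) {
  if (any(!is.finite(c(tc, tg, hdl))) || any(c(tc, tg, hdl) <= 0)) {
    stop("invalid record: lipid values must be finite and strictly positive",
         call. = FALSE)
  }
  on_lipid_drugs | tc >= 6.22 | tg >= 2.26 | hdl < 1.04
}

#' Classify obesity
#'
#' Body mass index weight / height^2 >= 28 kg/m^2, boundary inclusive.
#'
#' @param height_m height in metres, strictly positive.
#' @param weight_kg weight in kg, strictly positive.
#' @return logical vector.
#' @export
classify_obesity <- function(height_m, weight_kg) {
  if (any(!is.finite(c(height_m, weight_kg))) ||
      any(c(height_m, weight_kg) <= 0)) {
    stop("invalid record: height and weight must be finite and strictly positive",
         call. = FALSE)
  }
  weight_kg / height_m^2 >= 28
}

#' Classify physical exercise
#'
#' "sufficient": exercising >= 3 sessions a week for >= 30 minutes each, or
#' engaging in moderate-to-heavy physical labor (a single boolean flag;
#' no intensity scale is distinguished). Everything else is "lack".
#'
#' @param sessions_per_week integer >= 0.
#' @param minutes minutes per session, >= 0.
#' @param heavy_labor logical.
#' @return character vector, `"sufficient"` or `"lack"`.
#' @export
classify_exercise <- function(sessions_per_week, minutes, heavy_labor = FALSE) {
  if (any(sessions_per_week < 0) || any(minutes < 0)) {
    stop("invalid record: exercise frequency and duration must be non-negative",
         call. = FALSE)
  }
  ifelse((sessions_per_week >= 3 & minutes >= 30) | heavy_labor,
         "sufficient", "lack")
}

#' Classify drinking frequency
#'
#' Three levels: "frequent" (liquor >= 3 times/week and >= 100 mL each
#' time), "never" (no drinking at all), "occasional" otherwise.
#'
#' @param drinks logical, any alcohol consumption.
#' @param liquor_times_per_week integer >= 0.
#' @param ml_each mL per occasion, >= 0.
#' @return character vector in `{"never","occasional","frequent"}`.
#' @export
classify_drinking <- function(drinks, liquor_times_per_week = 0, ml_each = 0) {
  ifelse(liquor_times_per_week >= 3 & ml_each >= 100, "frequent",
         ifelse(!drinks & liquor_times_per_week == 0, "never", "occasional"))
}

#' Names of the six model risk factors
#'
#' The adjusted model uses exactly these six binary factors; the remaining
#' profile columns (sex, alcohol, obesity, dyslipidemia, cardiopathy) are
#' descriptive covariates only.
#'
#' @return character vector of length 6.
#' @export
model_factors <- function() {
  c("age_ge_60", "lack_of_exercise", "hypertension", "diabetes",
    "smoking", "family_history_cvd")
}

descriptive_factors <- function() {
  c("male", "alcohol", "obesity", "dyslipidemia", "cardiopathy")
}

participant_fields <- function() {
  c("id", "sex", "age_years", "sbp_mmHg", "dbp_mmHg", "height_m",
    "weight_kg", "fpg_mmol_L", "pg2h_mmol_L", "tc_mmol_L", "tg_mmol_L",
    "hdl_mmol_L", "smoker_6mo", "drink_frequency",
    "exercise_sessions_per_week", "exercise_minutes_per_session",
    "heavy_physical_labor", "dx_hypertension", "on_antihypertensives",
    "on_lipid_drugs", "on_glucose_drugs_or_insulin", "family_history_cvd",
    "cardiopathy", "cvd_case")
}

validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(participant_fields(), names(records))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$age_years < 40)) {
    bad <- records$id[records$age_years < 40]
    stop("invalid record id ", paste(bad, collapse = ", "),
         ": age below the inclusion criterion (40)", call. = FALSE)
  }
  if (anyDuplicated(records$id)) {
    stop("duplicate participant ids", call. = FALSE)
  }
  if (!all(records$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  if (!all(records$drink_frequency %in% c("never", "occasional", "frequent"))) {
    stop("drink_frequency must be never/occasional/frequent", call. = FALSE)
  }
  invisible(records)
}

#' Derive analysis-ready risk-factor profiles from raw records
#'
#' Applies every diagnostic classifier to a cohort of raw survey records and
#' returns one coded profile per participant: the six model factors
#' (age >= 60, lack of exercise, hypertension, diabetes, smoking >= 6 months
#' lifetime, family history of CVD), the descriptive covariates (male sex,
#' any alcohol, obesity, dyslipidemia, cardiopathy) and the binary CVD
#' outcome. Coding is deterministic and idempotent; classifier errors are
#' re-raised with the offending record ids attached.
#'
#' @param records data.frame with the raw participant columns (see
#'   [read_cohort_csv()] for the layout).
#' @return data.frame of coded profiles, one row per record, logical factor
#'   columns.
#' @export
derive_profiles <- function(records) {
  validate_records(records)
  cls <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop("while coding records [ids ", paste(utils::head(records$id, 5),
           collapse = ", "), if (nrow(records) > 5) ", ..." else "", "]: ",
           conditionMessage(e), call. = FALSE)
    })
  }
  data.frame(
    id = records$id,
    age_ge_60 = records$age_years >= 60,
    lack_of_exercise = cls(classify_exercise(
      records$exercise_sessions_per_week,
      records$exercise_minutes_per_session,
      records$heavy_physical_labor)) == "lack",
    hypertension = cls(classify_hypertension(
      records$dx_hypertension, records$on_antihypertensives,
      records$sbp_mmHg, records$dbp_mmHg)),
    diabetes = cls(classify_diabetes(
      records$fpg_mmol_L, records$pg2h_mmol_L,
      records$on_glucose_drugs_or_insulin)),
    smoking = as.logical(records$smoker_6mo),
    family_history_cvd = as.logical(records$family_history_cvd),
    sex = records$sex,
    male = records$sex == "male",
    alcohol = records$drink_frequency != "never",
    obesity = cls(classify_obesity(records$height_m, records$weight_kg)),
    dyslipidemia = cls(classify_dyslipidemia(
      records$tc_mmol_L, records$tg_mmol_L, records$hdl_mmol_L,
      records$on_lipid_drugs)),
    cardiopathy = as.logical(records$cardiopathy),
    cvd_case = as.logical(records$cvd_case),
    stringsAsFactors = FALSE
  )
}

#' Read a raw cohort CSV
#'
#' One row per participant; booleans serialised as 0/1, sex and drinking
#' frequency as their lower-case labels, missing 2-h glucose as an empty
#' cell.
#'
#' @param path CSV file path.
#' @return data.frame of raw participant records.
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  bool_cols <- c("smoker_6mo", "heavy_physical_labor", "dx_hypertension",
                 "on_antihypertensives", "on_lipid_drugs",
                 "on_glucose_drugs_or_insulin", "family_history_cvd",
                 "cardiopathy", "cvd_case")
  for (cc in intersect(bool_cols, names(raw))) raw[[cc]] <- raw[[cc]] != 0
  validate_records(raw)
}

#' Write a raw cohort CSV
#'
#' @param records data.frame of raw participant records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  out <- records
  for (cc in names(out)) if (is.logical(out[[cc]])) out[[cc]] <- as.integer(out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write coded profile CSVs
#'
#' Profiles are stored as id + 0/1 factor columns (+ sex label).
#'
#' @param profiles data.frame of coded profiles.
#' @param path file path.
#' @return the profiles (read) or `path` invisibly (write).
#' @export
write_profiles_csv <- function(profiles, path) {
  out <- profiles
  for (cc in names(out)) if (is.logical(out[[cc]])) out[[cc]] <- as.integer(out[[cc]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  bool_cols <- c(model_factors(), descriptive_factors(), "cvd_case")
  for (cc in intersect(bool_cols, names(raw))) raw[[cc]] <- raw[[cc]] != 0
  raw
}
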