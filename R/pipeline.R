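# End-to-end orchestration: simulate (or load) a cohort, split it, fit the
# six-factor Poisson model on the modeling half, build the score model,
# assess both halves, validate on the validation half, and render the
# resulting report tables deterministically.

#' Pipeline configuration
#'
#' @param n,seed,marginals,intercept,coefficients,correlation,p_cap passed to
#'   [generator_config()] when no cohort file is given.
#' @param cohort_csv optional path to a coded-profile CSV (see
#'   [read_profiles_csv()]); when set, simulation is skipped.
#' @param factors the scored/model factor names (columns of the design).
#' @param registry exposure registry used for the score model.
#' @param bands OR-to-score band table.
#' @param use_fitted_ors build the score model from the modeling-half fit
#'   (`TRUE`, the study procedure) or from the shipped reference ORs.
#' @param out_dir optional output directory; when set the report is rendered
#'   there by [render_report()] in every format.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(n = 2138, seed = 1,
                            marginals = default_marginals(),
                            intercept = -5.405,
                            coefficients = default_coefficients(),
                            correlation = NULL, p_cap = 0.999,
                            cohort_csv = NULL,
                            factors = model_factors(),
                            registry = default_exposure_registry(),
                            bands = default_score_bands(),
                            use_fitted_ors = TRUE,
                            out_dir = NULL) {
  if (!is.null(cohort_csv) && !file.exists(cohort_csv)) {
    stop("cohort file does not exist: ", cohort_csv, call. = FALSE)
  }
  if (length(factors) == 0) stop("factor list must be non-empty", call. = FALSE)
  structure(list(n = n, seed = seed, marginals = marginals,
                 intercept = intercept, coefficients = coefficients,
                 correlation = correlation, p_cap = p_cap,
                 cohort_csv = cohort_csv, factors = factors,
                 registry = registry, bands = bands,
                 use_fitted_ors = use_fitted_ors, out_dir = out_dir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

descriptive_table <- function(split, factors) {
  mod <- split$modeling; val <- split$validation
  all_p <- rbind(mod, val)
  rows <- lapply(factors, function(f) {
    x <- as.logical(all_p[[f]]); y <- as.logical(all_p$cvd_case)
    chi <- tryCatch(
      crude_chi2(two_by_two(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y))),
      error = function(e) list(chi2 = NA_real_, p = NA_real_))
    data.frame(factor = f,
               n_modeling = sum(mod[[f]]),
               pct_modeling = 100 * mean(as.logical(mod[[f]])),
               n_validation = sum(val[[f]]),
               pct_validation = 100 * mean(as.logical(val[[f]])),
               n_total = sum(x),
               prevalence_exposed = 100 * mean(y[x]),
               prevalence_unexposed = 100 * mean(y[!x]),
               chi2 = chi$chi2, p = chi$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

regression_table <- function(fit) {
  co <- fit$coefficients
  co$role <- ifelse(co$term == "(Intercept)", "constant", "factor")
  co
}

risk_level_table <- function(assessments) {
  lev <- risk_levels()
  counts <- table(factor(assessments$level, levels = lev))
  ill <- tapply(assessments$cvd_case, factor(assessments$level, levels = lev),
                function(v) sum(v, na.rm = TRUE))
  ill[is.na(ill)] <- 0
  data.frame(level = lev,
             n_enrolled = as.integer(counts),
             pct_enrolled = 100 * as.integer(counts) / nrow(assessments),
             n_ill = as.integer(ill),
             pct_ill = ifelse(counts > 0, 100 * as.integer(ill) / as.integer(counts), 0),
             stringsAsFactors = FALSE)
}

#' Run the full risk-index pipeline
#'
#' Stages: simulate (or load) -> odd/even split -> Poisson fit on the
#' modeling half -> score model (fitted or reference ORs + exposure
#' registry) -> assess both halves -> validation-half cut-point table,
#' Youden-optimal cut-off, ROC/AUC overall and by sex and age group, trend
#' chi-square per group and rank-sum comparison between groups. Fully
#' reproducible given the seed. A stage failure aborts with the stage name;
#' if an output directory was configured, partially rendered files are
#' removed.
#'
#' @param config a [pipeline_config()].
#' @return object of class `cvd_study_report` with elements `descriptive`,
#'   `regression`, `score_model`, `risk_levels` (per group), `trend`,
#'   `ranksum`, `cutpoints`, `optimal`, `roc`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))

  profiles <- if (!is.null(config$cohort_csv)) {
    stage("load", read_profiles_csv(config$cohort_csv))
  } else {
    stage("simulate", {
      gc_ <- generator_config(n = config$n, seed = config$seed,
                              marginals = config$marginals,
                              intercept = config$intercept,
                              coefficients = config$coefficients,
                              correlation = config$correlation,
                              p_cap = config$p_cap)
      generate_cohort(gc_)$profiles
    })
  }

  split <- stage("split", split_modeling_validation(profiles))

  fit <- stage("fit", fit_poisson_log_binary(
    split$modeling$cvd_case, split$modeling[config$factors]))

  model <- stage("score_model", {
    ors <- if (config$use_fitted_ors) or_map(fit) else
      reference_or_sets()$modeling_group[config$factors]
    build_score_model(ors, registry = config$registry, bands = config$bands,
                      provenance = if (config$use_fitted_ors)
                        "modeling-half Poisson fit" else "reference ORs")
  })

  assessed <- stage("assess", lapply(split, assess_cohort, model = model))

  validation <- stage("validate", {
    av <- assessed$validation
    grid <- achievable_cutoffs(model)
    ct <- cutpoint_table(av$r, av$cvd_case, grid)
    lvl_tables <- lapply(assessed, risk_level_table)
    trend <- lapply(lvl_tables, function(tb)
      tryCatch(trend_chi2(tb$n_enrolled, tb$n_ill),
               error = function(e) list(chi2_trend = NA_real_, p = NA_real_)))
    rs <- ranksum_ordinal(assessed$modeling$level, av$level)
    roc_total <- roc_auc(av$r, av$cvd_case)
    by_group <- function(flag, lab_true, lab_false) {
      ok <- function(v, y) sum(y[v]) > 0 && sum(!y[v]) > 0 &&
                           sum(y[!v]) > 0 && sum(!y[!v]) > 0
      if (!ok(flag, av$cvd_case)) return(NULL)
      cmp <- compare_auc(av$r[flag], av$cvd_case[flag],
                         av$r[!flag], av$cvd_case[!flag])
      stats::setNames(list(cmp), paste(lab_true, "vs", lab_false))
    }
    list(cutpoints = ct, optimal = optimal_cutoff(ct),
         risk_levels = lvl_tables, trend = trend, ranksum = rs,
         roc = c(list(total = roc_total),
                 if (!is.null(av$sex)) by_group(av$sex == "male", "male", "female"),
                 if (!is.null(av$age_ge_60)) by_group(av$age_ge_60, "age_ge_60", "age_40_59")))
  })

  manifest <- stage("manifest", {
    cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                                 auto_unbox = TRUE, digits = NA, force = TRUE,
                                 null = "null")
    tmp <- tempfile(); writeLines(cfg_json, tmp)
    h <- unname(tools::md5sum(tmp)); unlink(tmp)
    list(seed = config$seed, config_md5 = h,
         n_records = nrow(profiles),
         n_modeling = nrow(split$modeling),
         n_validation = nrow(split$validation),
         package_version = as.character(utils::packageVersion("cvdrisk")),
         r_version = paste(R.version$major, R.version$minor, sep = "."))
  })

  report <- structure(list(
    descriptive = descriptive_table(split, unique(c(config$factors,
      intersect(descriptive_factors(), names(profiles))))),
    regression = regression_table(fit),
    score_model = data.frame(factor = names(model$scores),
                             or = unname(model$ors),
                             score = unname(model$scores),
                             exposure_rate = model$registry$exposure_rate,
                             stringsAsFactors = FALSE),
    arop = model$arop,
    risk_levels = validation$risk_levels,
    trend = validation$trend,
    ranksum = validation$ranksum,
    cutpoints = validation$cutpoints,
    optimal = validation$optimal,
    roc = validation$roc,
    manifest = manifest), class = "cvd_study_report")

  if (!is.null(config$out_dir)) {
    written <- character()
    tryCatch({
      for (fmt in c("csv_bundle", "json", "markdown")) {
        written <- c(written, render_report(report, fmt, config$out_dir))
      }
    }, error = function(e) {
      unlink(written)
      stop("pipeline stage 'render' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  report
}

#' @export
print.cvd_study_report <- function(x, ...) {
  cat(sprintf("CVD risk-index study report: %d records (%d modeling / %d validation)\n",
              x$manifest$n_records, x$manifest$n_modeling, x$manifest$n_validation))
  cat(sprintf("AROP = %.2f; optimal cut-off R = %.2f (sens %.1f%%, spec %.1f%%, Youden %.3f)\n",
              x$arop, x$optimal$cutoff_r, 100 * x$optimal$sensitivity,
              100 * x$optimal$specificity, x$optimal$youden))
  cat(sprintf("validation AUC = %.3f (95%% CI %.3f~%.3f)\n",
              x$roc$total$auc, x$roc$total$ci_low, x$roc$total$ci_high))
  invisible(x)
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "-", formatC(x, format = "f", digits = digits))
}

md_table <- function(df, digits = 3) {
  cols <- names(df)
  body <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(cols, function(cc) {
      v <- df[[cc]][i]
      if (is.numeric(v)) fmt_num(v, if (v == round(v) && abs(v) < 1e6) 0 else digits)
      else as.character(v)
    }, character(1))
    paste0("| ", paste(cells, collapse = " | "), " |")
  }, character(1))
  c(paste0("| ", paste(cols, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
    body)
}

# Level labels used in report rendering (the published level table uses a
# slightly different naming than the classification table).
report_level_labels <- function() {
  c(very_low = "Very low", lower = "Relatively low", low = "Low",
    moderate = "General", high = "Relatively high", higher = "High",
    very_high = "Very high")
}

#' Render a study report to files
#'
#' Deterministic rendering: percentages to 1 decimal, ORs and R to 2-3
#' decimals. The three formats contain identical numbers.
#'
#' @param report a `cvd_study_report`.
#' @param format one of `"csv_bundle"`, `"json"`, `"markdown"`.
#' @param out_dir output directory (created if missing).
#' @return character vector of files written, invisibly.
#' @export
render_report <- function(report, format = c("csv_bundle", "json", "markdown"),
                          out_dir = ".") {
  stopifnot(inherits(report, "cvd_study_report"))
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lvl <- report_level_labels()

  cut_round <- report$cutpoints
  if (nrow(cut_round)) {
    cut_round$cutoff_r <- round(cut_round$cutoff_r, 2)
    for (cc in c("sensitivity", "specificity", "ppv", "npv")) {
      cut_round[[cc]] <- round(100 * cut_round[[cc]], 1)
    }
    cut_round$youden <- round(cut_round$youden, 3)
  }
  reg <- report$regression
  reg[c("beta", "se")] <- lapply(reg[c("beta", "se")], round, 3)
  reg[c("wald_chi2", "or", "ci_low", "ci_high")] <-
    lapply(reg[c("wald_chi2", "or", "ci_low", "ci_high")], round, 3)

  files <- character()
  if (format == "csv_bundle") {
    w <- function(df, name) {
      p <- file.path(out_dir, paste0(name, ".csv"))
      utils::write.csv(df, p, row.names = FALSE, na = "")
      p
    }
    files <- c(w(round_df(report$descriptive, 1), "descriptive"),
               w(reg, "regression"),
               w(report$score_model, "score_model"),
               w(transform(report$risk_levels$modeling, level = lvl[level]),
                 "risk_levels_modeling"),
               w(transform(report$risk_levels$validation, level = lvl[level]),
                 "risk_levels_validation"),
               w(cut_round, "cutpoints"))
  } else if (format == "json") {
    p <- file.path(out_dir, "report.json")
    jsonlite::write_json(list(
      descriptive = round_df(report$descriptive, 1),
      regression = reg,
      score_model = report$score_model,
      arop = round(report$arop, 2),
      risk_levels = lapply(report$risk_levels, function(tb)
        transform(round_df(tb, 1), level = unname(lvl[level]))),
      trend = report$trend, ranksum = report$ranksum,
      cutpoints = cut_round,
      optimal = cut_round[which(round(report$optimal$cutoff_r, 2) ==
                                  cut_round$cutoff_r), ],
      roc = report$roc, manifest = report$manifest),
      p, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
    files <- p
  } else {
    p <- file.path(out_dir, "report.md")
    lines <- c("# CVD risk-index study report", "",
               sprintf("- records: %d (modeling %d / validation %d)",
                       report$manifest$n_records, report$manifest$n_modeling,
                       report$manifest$n_validation),
               sprintf("- seed: %s; config md5: %s", report$manifest$seed,
                       report$manifest$config_md5),
               sprintf("- AROP: %.2f", report$arop), "",
               "## Factor descriptives", md_table(round_df(report$descriptive, 1)), "",
               "## Poisson regression (modeling half)", md_table(reg), "",
               "## Score model", md_table(report$score_model), "",
               "## Risk levels (modeling half)",
               md_table(transform(round_df(report$risk_levels$modeling, 1),
                                  level = unname(lvl[level]))), "",
               "## Risk levels (validation half)",
               md_table(transform(round_df(report$risk_levels$validation, 1),
                                  level = unname(lvl[level]))), "",
               sprintf("Trend chi2: modeling %.3f (p = %.4g), validation %.3f (p = %.4g); rank-sum z = %.3f (p = %.3f)",
                       report$trend$modeling$chi2_trend, report$trend$modeling$p,
                       report$trend$validation$chi2_trend, report$trend$validation$p,
                       report$ranksum$z, report$ranksum$p), "")
    if (nrow(cut_round)) {
      lines <- c(lines, "## Cut-point performance (validation half)",
                 md_table(cut_round), "",
                 sprintf("Optimal cut-off: R = %.2f (Youden %.3f)",
                         report$optimal$cutoff_r, report$optimal$youden), "",
                 sprintf("Validation AUC: %.3f (95%% CI %.3f~%.3f)",
                         report$roc$total$auc, report$roc$total$ci_low,
                         report$roc$total$ci_high))
    } else {
      lines <- c(lines,
                 "Cut-point and risk-level validation omitted: no cut-offs available.")
    }
    writeLines(lines, p)
    files <- p
  }
  invisible(files)
}

round_df <- function(df, digits) {
  df[] <- lapply(df, function(v) if (is.numeric(v)) round(v, digits) else v)
  df
}
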