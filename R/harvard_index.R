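# The risk-index core: banded conversion of odds ratios into integer risk
# scores, the exposure-weighted population average score (AROP), the
# individual score sum (RCI), the population-normalised ratio R = RCI/AROP,
# and its seven-level classification.

#' Default OR-to-score conversion bands
#'
#' The published conversion standard prints one-decimal band edges
#' (0.9~1.1 -> 0, 1.1~1.4 -> 5, 1.5~2.9 -> 10, 3.0~6.9 -> 25, >= 7.0 -> 50,
#' mirrored on the protective side). The printed edges are one-decimal
#' renderings of contiguous ranges, so the bands are implemented as
#' contiguous half-open intervals partitioning (0, Inf); every shipped OR
#' lands in the same band under either reading. Protective bands carry
#' negative scores, harmful bands positive ones, the null band zero.
#'
#' @return data.frame with columns `lower`, `upper` (half-open
#'   `[lower, upper)`), `score`, `strength`.
#' @export
default_score_bands <- function() {
  data.frame(
    lower = c(0,   0.2, 0.4, 0.7, 0.9, 1.1, 1.5, 3.0, 7.0),
    upper = c(0.2, 0.4, 0.7, 0.9, 1.1, 1.5, 3.0, 7.0, Inf),
    score = c(-50, -25, -10,  -5,   0,   5,  10,  25,  50),
    strength = c("very strong", "strong", "moderate", "weak",
                 "not significant", "weak", "moderate", "strong",
                 "very strong"),
    stringsAsFactors = FALSE)
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands),
            all(c("lower", "upper", "score") %in% names(bands)))
  o <- order(bands$lower)
  bands <- bands[o, ]
  if (bands$lower[1] != 0 || !is.infinite(bands$upper[nrow(bands)]) ||
      any(bands$upper[-nrow(bands)] != bands$lower[-1])) {
    stop("score bands must partition (0, Inf) as contiguous half-open intervals",
         call. = FALSE)
  }
  bands
}

#' Convert an odds ratio to a banded risk score
#'
#' @param or positive odds ratio(s).
#' @param bands band table, default [default_score_bands()].
#' @return integer score(s): 0 on the null band, positive for harmful,
#'   negative for protective associations.
#' @export
#' @examples
#' score_from_or(3.171)  # 25
#' score_from_or(2.306)  # 10
#' score_from_or(0.5)    # -10
score_from_or <- function(or, bands = default_score_bands()) {
  if (any(!is.finite(or)) || any(or <= 0)) {
    stop("odds ratios must be finite and strictly positive", call. = FALSE)
  }
  bands <- validate_bands(bands)
  idx <- findInterval(or, bands$lower)  # half-open [lower, upper)
  bands$score[idx]
}

#' Reference odds-ratio sets
#'
#' The methodology reports two labelled OR sets for the same six factors:
#' the modeling-half fit that the shipped score model is built from, and the
#' full-sample fit. They differ slightly (e.g. age 3.171 vs 3.284) and are
#' both exposed rather than conflated.
#'
#' @return list of two named numeric vectors, `modeling_group` and
#'   `full_sample`, over [model_factors()].
#' @export
reference_or_sets <- function() {
  list(
    modeling_group = c(age_ge_60 = 3.171, lack_of_exercise = 2.306,
                       hypertension = 2.436, diabetes = 3.220,
                       smoking = 1.877, family_history_cvd = 2.315),
    full_sample = c(age_ge_60 = 3.284, lack_of_exercise = 2.306,
                    hypertension = 2.510, diabetes = 3.194,
                    smoking = 1.949, family_history_cvd = 2.315))
}

#' Default exposure registry
#'
#' Reference-population exposure rates for the six scored factors, each with
#' its source. Note the physical-exercise entry: the published registry
#' carries 0.82 — the proportion who exercise *regularly* — although the
#' scored factor is *lack* of exercise; the published AROP (22.20) is only
#' reproducible with 0.82, so 0.82 ships as the default and the
#' inconsistency is documented rather than silently corrected.
#'
#' @return data.frame with columns `factor`, `exposure_rate`, `source`.
#' @export
default_exposure_registry <- function() {
  data.frame(
    factor = model_factors(),
    exposure_rate = c(0.17, 0.82, 0.28, 0.11, 0.28, 0.14),
    source = c("China health statistics yearbook 2019 (aged >= 60, 2018)",
               "study sample (proportion exercising regularly)",
               "Chinese hypertension guidelines, 2018 revision (2017 rate)",
               "Chinese type 2 diabetes guidelines, 2017 edition (2016 rate)",
               "Chinese stroke prevention and treatment report 2017 (2016 rate)",
               "study sample (family history of CVD)"),
    stringsAsFactors = FALSE)
}

#' Build a risk score model from odds ratios and exposure rates
#'
#' Converts each factor's OR to a banded score RC_f and computes the
#' population average risk score AROP = sum_f ER_f * RC_f, the normalising
#' denominator of the index.
#'
#' @param or_map named positive numeric vector, one OR per factor.
#' @param registry exposure registry (`factor`, `exposure_rate` in (0,1));
#'   every scored factor must have exactly one entry.
#' @param bands OR-to-score band table.
#' @param provenance free-text label of the OR set used.
#' @return object of class `risk_score_model`: `$scores` (named integer
#'   vector), `$ors`, `$registry`, `$arop`, `$bands`, `$provenance`.
#' @export
build_score_model <- function(or_map, registry = default_exposure_registry(),
                              bands = default_score_bands(),
                              provenance = "unspecified") {
  if (is.null(names(or_map))) stop("or_map must be named by factor", call. = FALSE)
  missing_er <- setdiff(names(or_map), registry$factor)
  if (length(missing_er)) {
    stop("no exposure rate registered for factor(s): ",
         paste(missing_er, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(registry$factor)) {
    stop("duplicate exposure-registry entries", call. = FALSE)
  }
  registry <- registry[match(names(or_map), registry$factor), ]
  if (any(registry$exposure_rate < 0) || any(registry$exposure_rate > 1)) {
    stop("exposure rates must lie in [0, 1]", call. = FALSE)
  }
  scores <- stats::setNames(score_from_or(or_map, bands), names(or_map))
  arop <- sum(registry$exposure_rate * scores)
  structure(list(scores = scores, ors = or_map, registry = registry,
                 arop = arop, bands = validate_bands(bands),
                 provenance = provenance),
            class = "risk_score_model")
}

#' The shipped default score model
#'
#' Built from the modeling-group reference ORs and the default exposure
#' registry; its AROP is 22.20 points.
#'
#' @return a `risk_score_model`.
#' @export
default_score_model <- function() {
  build_score_model(reference_or_sets()$modeling_group,
                    provenance = "modeling_group reference ORs")
}

#' @export
print.risk_score_model <- function(x, ...) {
  cat(sprintf("risk score model (%s), AROP = %.2f\n", x$provenance, x$arop))
  print(data.frame(factor = names(x$scores), or = unname(x$ors),
                   score = unname(x$scores),
                   exposure_rate = x$registry$exposure_rate),
        row.names = FALSE)
  invisible(x)
}

#' Individual cumulative risk score (RCI)
#'
#' Sum of the model's factor scores over the factors an individual carries;
#' absent factors contribute 0.
#'
#' @param profiles data.frame (or logical matrix) containing one 0/1 or
#'   logical column per scored factor.
#' @param model a `risk_score_model`.
#' @return numeric vector of score sums.
#' @export
compute_rci <- function(profiles, model) {
  stopifnot(inherits(model, "risk_score_model"))
  need <- names(model$scores)
  miss <- setdiff(need, colnames(profiles))
  if (length(miss)) {
    stop("profiles lack scored factor column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(as.data.frame(profiles)[need])
  storage.mode(x) <- "double"
  drop(x %*% model$scores)
}

#' Individual risk ratio R
#'
#' R = RCI / AROP: the individual's score sum relative to the population
#' average. Kept unrounded internally; reports render it to 2 decimals.
#'
#' @param rci numeric score sum(s).
#' @param model a `risk_score_model` with positive AROP.
#' @return numeric vector.
#' @export
compute_r <- function(rci, model) {
  stopifnot(inherits(model, "risk_score_model"))
  if (!is.finite(model$arop) || model$arop <= 0) {
    stop("AROP must be strictly positive to normalise individual scores",
         call. = FALSE)
  }
  rci / model$arop
}

#' Risk level names, in increasing order
#' @return character vector of the seven levels.
#' @export
risk_levels <- function() {
  c("very_low", "lower", "low", "moderate", "high", "higher", "very_high")
}

#' Classify the individual risk ratio into seven levels
#'
#' The published level table leaves its boundaries open (and R = 0
#' unassigned); classification must be total, so lower-closed intervals are
#' used: very_low R <= 0; lower (0, 0.5); low [0.5, 0.9); moderate
#' [0.9, 1.1); high [1.1, 2.0); higher [2.0, 5.0); very_high R >= 5.0.
#' Zero-score individuals (R = 0) therefore fall in "very_low", the only
#' reading under which that stratum is populated when all scores are
#' positive.
#'
#' @param r numeric risk ratio(s).
#' @return ordered factor over [risk_levels()].
#' @export
classify_risk_level <- function(r) {
  stopifnot(all(is.finite(r)))
  cuts <- c(-Inf, 0, 0.5, 0.9, 1.1, 2.0, 5.0)
  # lower-closed intervals [cut_i, cut_{i+1}); the first absorbs r <= 0
  idx <- findInterval(r, cuts)
  idx[r <= 0] <- 1
  factor(risk_levels()[idx], levels = risk_levels(), ordered = TRUE)
}

#' Achievable cut-off grid of a score model
#'
#' Enumerates all 2^k factor subsets, forms every achievable RCI, and
#' returns the distinct positive R = RCI/AROP values in increasing order —
#' the natural cut-off grid for the cut-point table.
#'
#' @param model a `risk_score_model`.
#' @return sorted numeric vector of achievable positive R values.
#' @export
achievable_cutoffs <- function(model) {
  stopifnot(inherits(model, "risk_score_model"))
  k <- length(model$scores)
  subsets <- as.matrix(expand.grid(rep(list(0:1), k)))
  sums <- unique(drop(subsets %*% model$scores))
  sort(sums[sums > 0]) / model$arop
}

#' Assess a cohort against a score model
#'
#' @param profiles coded profile data.frame (must include the scored factor
#'   columns; `id` and `cvd_case` are carried through when present).
#' @param model a `risk_score_model`.
#' @return data.frame with `id`, `rci`, `r`, `level` (+ `cvd_case` if
#'   available).
#' @export
assess_cohort <- function(profiles, model) {
  rci <- compute_rci(profiles, model)
  r <- compute_r(rci, model)
  out <- data.frame(
    id = if ("id" %in% names(profiles)) profiles$id else seq_along(rci),
    rci = rci, r = r, level = classify_risk_level(r),
    stringsAsFactors = FALSE)
  if ("cvd_case" %in% names(profiles)) out$cvd_case <- as.logical(profiles$cvd_case)
  if ("sex" %in% names(profiles)) out$sex <- profiles$sex
  if ("age_ge_60" %in% names(profiles)) out$age_ge_60 <- as.logical(profiles$age_ge_60)
  out
}
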