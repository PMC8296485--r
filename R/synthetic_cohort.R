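# Seeded synthetic cohorts with the statistical structure of the source
# community survey: configurable binary factor marginals, a log-link
# relative-risk outcome model on the six adjusted factors, and the
# deterministic odd/even modeling/validation split.

#' Default factor marginals
#'
#' Full-sample prevalences of the coded factors (pooled over both study
#' halves, which were split at random): proportion aged >= 60, lacking
#' exercise, smoking, hypertensive, diabetic, with a family history, male,
#' drinking, obese, dyslipidemic, with cardiopathy.
#'
#' @return named numeric vector of probabilities.
#' @export
default_marginals <- function() {
  c(age_ge_60 = 0.727, lack_of_exercise = 0.182, smoking = 0.150,
    hypertension = 0.553, diabetes = 0.143, family_history_cvd = 0.141,
    male = 0.384, alcohol = 0.142, obesity = 0.219, dyslipidemia = 0.432,
    cardiopathy = 0.123)
}

#' Default adjusted log-risk coefficients
#'
#' The six-factor outcome model: log-risk (Poisson, log link) coefficients
#' for age >= 60, lack of exercise, smoking, hypertension, diabetes and
#' family history, with baseline intercept -5.405.
#'
#' @return named numeric vector over [model_factors()].
#' @export
default_coefficients <- function() {
  c(age_ge_60 = 1.189, lack_of_exercise = 0.836, smoking = 0.667,
    hypertension = 0.920, diabetes = 1.161, family_history_cvd = 0.839)
}

#' Synthetic cohort generator configuration
#'
#' @param n cohort size (the study enrolled 2138; even n gives a clean
#'   half/half split).
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @param marginals named probabilities in (0,1) for every simulated factor.
#' @param intercept baseline log risk.
#' @param coefficients named log risk ratios; names select which factors
#'   enter the outcome model.
#' @param correlation optional symmetric positive-definite latent (Gaussian
#'   copula) correlation matrix whose dimnames are a subset of the marginal
#'   factor names; `NULL` means independent factors.
#' @param p_cap cap applied to exp(linear predictor): the log-link risk
#'   model is not a probability for extreme covariate patterns (the
#'   all-factor pattern exceeds 1), so risks are truncated and the number
#'   of capped draws is reported.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n = 2138, seed = NULL,
                             marginals = default_marginals(),
                             intercept = -5.405,
                             coefficients = default_coefficients(),
                             correlation = NULL, p_cap = 0.999) {
  stopifnot(length(n) == 1, n >= 1, n == round(n))
  if (is.null(names(marginals)) || anyNA(names(marginals))) {
    stop("marginals must be a named vector", call. = FALSE)
  }
  if (any(marginals <= 0) || any(marginals >= 1)) {
    stop("marginal probabilities must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (is.null(names(coefficients)) || !all(is.finite(coefficients))) {
    stop("coefficients must be a named finite vector", call. = FALSE)
  }
  if (!all(names(coefficients) %in% names(marginals))) {
    stop("every outcome-model factor needs a marginal: missing ",
         paste(setdiff(names(coefficients), names(marginals)), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(correlation)) {
    if (!is.matrix(correlation) || nrow(correlation) != ncol(correlation) ||
        is.null(rownames(correlation)) ||
        !identical(rownames(correlation), colnames(correlation)) ||
        !all(rownames(correlation) %in% names(marginals)) ||
        !isTRUE(all.equal(correlation, t(correlation))) ||
        any(abs(diag(correlation) - 1) > 1e-12)) {
      stop("correlation must be a symmetric matrix with unit diagonal, named by factors",
           call. = FALSE)
    }
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) {
      stop("correlation matrix is not positive definite", call. = FALSE)
    }
  }
  stopifnot(p_cap > 0, p_cap <= 1)
  structure(list(n = as.integer(n), seed = seed, marginals = marginals,
                 intercept = intercept, coefficients = coefficients,
                 correlation = correlation, p_cap = p_cap),
            class = "generator_config")
}

draw_factors <- function(config) {
  n <- config$n
  m <- config$marginals
  x <- matrix(NA, n, length(m), dimnames = list(NULL, names(m)))
  if (!is.null(config$correlation)) {
    corr_f <- rownames(config$correlation)
    L <- chol(config$correlation)
    z <- matrix(stats::rnorm(n * length(corr_f)), n) %*% L
    x[, corr_f] <- sweep(z, 2, stats::qnorm(m[corr_f]), "<")
    rest <- setdiff(names(m), corr_f)
  } else {
    rest <- names(m)
  }
  for (f in rest) x[, f] <- stats::runif(n) < m[f]
  x
}

#' Generate a synthetic cohort
#'
#' Draws coded risk-factor profiles from the configured marginals
#' (independently, or through a Gaussian-copula latent correlation) and the
#' binary CVD outcome from the log-link relative-risk model
#' p = min(exp(intercept + sum beta_f x_f), p_cap). Identical
#' (configuration, seed) pairs give identical cohorts. Record order is the
#' enrolment order used by [split_modeling_validation()].
#'
#' @param config a [generator_config()].
#' @return object of class `synthetic_cohort`: `$profiles` (data.frame in
#'   the coded-profile layout), `$config`, `$prevalence` (realised),
#'   `$n_capped` (draws whose model risk exceeded `p_cap`).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  x <- draw_factors(config)
  beta <- config$coefficients
  lp <- config$intercept + x[, names(beta), drop = FALSE] %*% beta
  p_raw <- exp(drop(lp))
  n_capped <- sum(p_raw > config$p_cap)
  if (n_capped > 0) {
    warning(sprintf("%d of %d model risks exceeded p_cap = %g and were truncated",
                    n_capped, config$n, config$p_cap), call. = FALSE)
  }
  p <- pmin(p_raw, config$p_cap)
  y <- stats::runif(config$n) < p
  profiles <- data.frame(id = seq_len(config$n), as.data.frame(x),
                         stringsAsFactors = FALSE)
  profiles$sex <- ifelse(profiles$male, "male", "female")
  profiles$cvd_case <- y
  structure(list(profiles = profiles, config = config,
                 prevalence = mean(y), n_capped = n_capped),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: n = %d, realised CVD prevalence = %.3f%s\n",
              x$config$n, x$prevalence,
              if (x$n_capped > 0) sprintf(" (%d capped risks)", x$n_capped) else ""))
  invisible(x)
}

#' Exact expected prevalence under a generator configuration
#'
#' Closed-form expectation of the outcome under independent factors: the sum
#' over all 2^k covariate patterns of P(pattern) * min(exp(lp), p_cap).
#' Only defined for independent configurations.
#'
#' @param config a [generator_config()] with `correlation = NULL`.
#' @return expected prevalence in (0,1).
#' @export
expected_prevalence <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$correlation)) {
    stop("closed-form prevalence requires independent factors", call. = FALSE)
  }
  beta <- config$coefficients
  m <- config$marginals[names(beta)]
  cells <- as.matrix(expand.grid(rep(list(0:1), length(beta))))
  colnames(cells) <- names(beta)
  p_cell <- apply(cells, 1, function(x) prod(ifelse(x == 1, m, 1 - m)))
  risk <- pmin(exp(config$intercept + drop(cells %*% beta)), config$p_cap)
  sum(p_cell * risk)
}

#' Split a cohort into modeling and validation halves
#'
#' Deterministic alternating split on enrolment order: 1-based positions
#' 1, 3, 5, ... form the modeling group, 2, 4, 6, ... the validation group.
#' Every record is kept exactly once; with even n the halves are equal
#' (2138 records give 1069 + 1069).
#'
#' @param cohort a `synthetic_cohort` or a profiles data.frame in enrolment
#'   order.
#' @return list with `modeling` and `validation` data.frames.
#' @export
split_modeling_validation <- function(cohort) {
  profiles <- if (inherits(cohort, "synthetic_cohort")) cohort$profiles else cohort
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 1)
  idx <- seq_len(nrow(profiles))
  list(modeling = profiles[idx %% 2 == 1, , drop = FALSE],
       validation = profiles[idx %% 2 == 0, , drop = FALSE])
}
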