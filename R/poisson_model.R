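# Log-link Poisson regression on the binary CVD indicator.
#
# With a log link and a binary outcome the exponentiated coefficients are
# adjusted prevalence (risk) ratios; the source methodology labels them OR
# and we keep that name in outputs. The fit is plain IRLS (Fisher scoring),
# tracking the log-likelihood so non-convergence is declared rather than
# silently returning a diverged estimate.

#' Fit a log-link Poisson model to a binary outcome
#'
#' Maximises the Poisson log-likelihood sum(y * eta - exp(eta)) by
#' iteratively reweighted least squares. Confidence intervals are
#' large-sample Wald intervals exp(beta +/- 1.96 se); standard errors are
#' model-based (inverse Fisher information) by default, with an optional
#' robust (sandwich) variance.
#'
#' @param outcomes logical or 0/1 numeric vector.
#' @param design data.frame or matrix of 0/1 factor indicators; an intercept
#'   is added internally, so no column may be constant or duplicated
#'   (rank-deficient designs raise an error naming the offending columns).
#' @param robust use the sandwich variance instead of the Fisher one.
#' @param max_iter,tol IRLS iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return object of class `cvd_poisson_fit`: `$coefficients` (one row per
#'   term incl. the intercept: beta, se, Wald chi-square, p, OR and 95% CI),
#'   `$n`, `$converged`, `$iterations`, `$loglik`, `$loglik_trace`.
#' @export
fit_poisson_log_binary <- function(outcomes, design, robust = FALSE,
                                   max_iter = 100, tol = 1e-10) {
  y <- as.numeric(outcomes)
  stopifnot(all(y %in% c(0, 1)))
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("design and outcome lengths differ", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, X)

  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (mean(y) == 0) stop("no cases in the data; model is undefined", call. = FALSE)

  beta <- c(log(mean(y)), rep(0, ncol(X) - 1))
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - exp(eta))
  trace <- ll
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    mu <- exp(eta)
    w <- mu                      # Poisson log-link working weight
    z <- eta + (y - mu) / mu     # working response
    fit <- tryCatch(
      solve(crossprod(X, w * X), crossprod(X, w * z)),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit))) break
    beta <- drop(fit)
    eta <- drop(X %*% beta)
    ll_new <- sum(y * eta - exp(eta))
    trace <- c(trace, ll_new)
    if (!is.finite(ll_new)) break
    # separation: a coefficient drifting beyond |log risk| = 20 means the
    # MLE lies at infinity; declare non-convergence instead of a numerical
    # "convergence" at an absurd estimate
    if (max(abs(beta)) > 20) break
    if (abs(ll_new - ll) / (abs(ll) + 0.1) < tol) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }

  mu <- exp(drop(X %*% beta))
  info <- crossprod(X, mu * X)
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  if (robust && !anyNA(vcov)) {
    meat <- crossprod(X, (y - mu)^2 * X)
    vcov <- vcov %*% meat %*% vcov
  }
  se <- sqrt(diag(vcov))
  wald <- (beta / se)^2
  coefs <- data.frame(
    term = colnames(X), beta = beta, se = se, wald_chi2 = wald,
    p_value = stats::pchisq(wald, df = 1, lower.tail = FALSE),
    or = exp(beta), ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!converged) {
    warning("IRLS did not converge in ", iter,
            " iterations; estimates are flagged, not trustworthy", call. = FALSE)
  }
  structure(list(coefficients = coefs, n = length(y), converged = converged,
                 iterations = iter, loglik = ll, loglik_trace = trace,
                 robust = robust),
            class = "cvd_poisson_fit")
}

#' @export
print.cvd_poisson_fit <- function(x, ...) {
  cat(sprintf("log-link Poisson fit on %d records (%s, %d IRLS iterations)\n",
              x$n, if (x$converged) "converged" else "NOT CONVERGED",
              x$iterations))
  out <- x$coefficients
  out[-1] <- lapply(out[-1], signif, 4)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Extract the odds-ratio map from a fit
#'
#' @param fit a `cvd_poisson_fit`.
#' @return named vector of exponentiated coefficients, intercept excluded.
#' @export
or_map <- function(fit) {
  stopifnot(inherits(fit, "cvd_poisson_fit"))
  co <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  stats::setNames(co$or, co$term)
}

#' Two-by-two exposure-outcome table
#'
#' @param exposed_cases,exposed_noncases,unexposed_cases,unexposed_noncases
#'   non-negative integer counts.
#' @return object of class `two_by_two`.
#' @export
two_by_two <- function(exposed_cases, exposed_noncases,
                       unexposed_cases, unexposed_noncases) {
  counts <- c(exposed_cases = exposed_cases, exposed_noncases = exposed_noncases,
              unexposed_cases = unexposed_cases,
              unexposed_noncases = unexposed_noncases)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("empty table", call. = FALSE)
  structure(as.list(counts), class = "two_by_two")
}

#' Pearson chi-square for a 2x2 table
#'
#' Uncorrected (no continuity correction) Pearson statistic with p-value
#' from the 1-df chi-square distribution. A zero row or column margin leaves
#' the statistic undefined and raises an error.
#'
#' @param tab a [two_by_two()] table.
#' @return list with `chi2` and `p`.
#' @export
crude_chi2 <- function(tab) {
  stopifnot(inherits(tab, "two_by_two"))
  a <- tab$exposed_cases; b <- tab$exposed_noncases
  c_ <- tab$unexposed_cases; d <- tab$unexposed_noncases
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) {
    stop("chi-square undefined: a table margin is zero", call. = FALSE)
  }
  chi2 <- n * (a * d - b * c_)^2 / prod(margins)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}
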