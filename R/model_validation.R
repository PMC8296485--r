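# Validation of a fitted risk index: cut-point performance, Youden-optimal
# threshold, ROC/AUC with DeLong confidence intervals and two-sample
# comparison, Cochran-Armitage trend test across ordered risk levels, and
# the tie-corrected Wilcoxon rank-sum test on ordinal level codes.

check_binary_groups <- function(r_values, outcomes) {
  y <- as.logical(outcomes)
  stopifnot(length(r_values) == length(y), !anyNA(r_values), !anyNA(y))
  if (!any(y) || all(y)) {
    stop("need at least one case and one control", call. = FALSE)
  }
  y
}

#' Confusion metrics at a single cut-off
#'
#' Test-positive means r >= cutoff (the grid convention under which every
#' achievable score is its own cut-off). Predictive values with a zero
#' denominator are reported as `NA`, not 0.
#'
#' @param r_values numeric risk ratios.
#' @param outcomes logical (or 0/1) case indicator; both classes must occur.
#' @param cutoff threshold.
#' @return one-row data.frame: `cutoff_r`, `sensitivity`, `specificity`,
#'   `youden`, `ppv`, `npv` (proportions in `[0,1]`) plus the four counts.
#' @export
confusion_at_cutoff <- function(r_values, outcomes, cutoff) {
  y <- check_binary_groups(r_values, outcomes)
  pos <- r_values >= cutoff
  tp <- sum(pos & y);  fn <- sum(!pos & y)
  fp <- sum(pos & !y); tn <- sum(!pos & !y)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  data.frame(cutoff_r = cutoff, sensitivity = sens, specificity = spec,
             youden = sens + spec - 1,
             ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
             npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
             tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Youden index from sensitivity and specificity
#'
#' @param sensitivity,specificity proportions in `[0,1]`.
#' @return sensitivity + specificity - 1.
#' @export
youden_index <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  sensitivity + specificity - 1
}

#' Cut-point performance table
#'
#' One [confusion_at_cutoff()] row per cut-off. When `cutoffs` is omitted a
#' score model must be supplied and its achievable-R grid
#' ([achievable_cutoffs()]) is used.
#'
#' @param r_values,outcomes as in [confusion_at_cutoff()].
#' @param cutoffs numeric vector of thresholds (may be empty).
#' @param model optional `risk_score_model` supplying the default grid.
#' @return data.frame of cut-point rows.
#' @export
cutpoint_table <- function(r_values, outcomes, cutoffs = NULL, model = NULL) {
  if (is.null(cutoffs)) {
    if (is.null(model)) stop("supply cutoffs or a score model", call. = FALSE)
    cutoffs <- achievable_cutoffs(model)
  }
  if (length(cutoffs) == 0) {
    return(confusion_at_cutoff(r_values, outcomes, 0)[0, ])
  }
  do.call(rbind, lapply(cutoffs, function(ct)
    confusion_at_cutoff(r_values, outcomes, ct)))
}

#' Youden-optimal cut-off row
#'
#' Maximises the Youden index; ties are broken toward the larger cut-off
#' (higher specificity).
#'
#' @param table a [cutpoint_table()] result with at least one row.
#' @return the optimal row.
#' @export
optimal_cutoff <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1)
  best <- table[table$youden == max(table$youden), , drop = FALSE]
  best[which.max(best$cutoff_r), , drop = FALSE]
}

auc_components <- function(cases, controls) {
  sc <- sort(controls)
  n <- length(sc)
  le <- findInterval(cases, sc)                   # controls <= case
  lt <- findInterval(cases, sc, left.open = TRUE) # controls <  case
  v10 <- (lt + 0.5 * (le - lt)) / n
  sx <- sort(cases)
  m <- length(sx)
  ge <- m - findInterval(controls, sx, left.open = TRUE) # cases > control or ==
  gt <- m - findInterval(controls, sx)                   # cases > control
  v01 <- (gt + 0.5 * (ge - gt)) / m
  list(v10 = v10, v01 = v01)
}

#' ROC area with DeLong confidence interval
#'
#' AUC as the Mann-Whitney statistic (ties counted one half) and a 95%
#' confidence interval from the DeLong structural-component variance,
#' clipped to `[0,1]`.
#'
#' @param r_values numeric scores.
#' @param outcomes logical (or 0/1) case indicator; both classes required.
#' @return object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `var_auc`, `n_cases`, `n_controls`.
#' @export
roc_auc <- function(r_values, outcomes) {
  y <- check_binary_groups(r_values, outcomes)
  cases <- r_values[y]; controls <- r_values[!y]
  comp <- auc_components(cases, controls)
  auc <- mean(comp$v10)
  m <- length(cases); n <- length(controls)
  var_auc <- (if (m > 1) stats::var(comp$v10) / m else 0) +
             (if (n > 1) stats::var(comp$v01) / n else 0)
  half <- 1.96 * sqrt(var_auc)
  structure(list(auc = auc, ci_low = max(0, auc - half),
                 ci_high = min(1, auc + half), var_auc = var_auc,
                 n_cases = m, n_controls = n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f~%.3f), %d cases / %d controls\n",
              x$auc, x$ci_low, x$ci_high, x$n_cases, x$n_controls))
  invisible(x)
}

#' Empirical ROC curve coordinates
#'
#' (1 - specificity, sensitivity) at every distinct threshold, ordered so the
#' trapezoidal area equals the Mann-Whitney AUC — used as the second route
#' of the two-route AUC check and for plotting.
#'
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(r_values, outcomes) {
  y <- check_binary_groups(r_values, outcomes)
  th <- sort(unique(r_values))
  rows <- lapply(th, function(t) {
    pos <- r_values >= t
    data.frame(threshold = t, fpr = sum(pos & !y) / sum(!y),
               tpr = sum(pos & y) / sum(y))
  })
  rbind(data.frame(threshold = -Inf, fpr = 1, tpr = 1),
        do.call(rbind, rows),
        data.frame(threshold = Inf, fpr = 0, tpr = 0))
}

#' Compare the AUCs of two independent groups
#'
#' Two-sided unpaired DeLong z-test: z = (AUC_a - AUC_b) /
#' sqrt(var_a + var_b) with variances from each group's structural
#' components.
#'
#' @param r_a,outcomes_a scores and case indicator of group a.
#' @param r_b,outcomes_b same for group b.
#' @return list with `auc_a`, `auc_b`, `z`, `p`.
#' @export
compare_auc <- function(r_a, outcomes_a, r_b, outcomes_b) {
  ra <- roc_auc(r_a, outcomes_a)
  rb <- roc_auc(r_b, outcomes_b)
  v <- ra$var_auc + rb$var_auc
  d <- ra$auc - rb$auc
  if (v <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
  }
  list(auc_a = ra$auc, auc_b = rb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Cochran-Armitage trend test over ordered level counts
#'
#' Linear-trend chi-square with equally spaced integer scores over the
#' supplied ordered levels; levels with zero enrolment are dropped. With two
#' levels the statistic reduces to the uncorrected Pearson chi-square of the
#' 2x2 table.
#'
#' @param n_enrolled,n_ill integer vectors, ordered from lowest to highest
#'   level; `n_ill <= n_enrolled` elementwise.
#' @return list with `chi2_trend`, `p`, `df` (= 1).
#' @export
trend_chi2 <- function(n_enrolled, n_ill) {
  stopifnot(length(n_enrolled) == length(n_ill),
            all(n_ill >= 0), all(n_ill <= n_enrolled))
  keep <- n_enrolled > 0
  n <- n_enrolled[keep]; r <- n_ill[keep]
  if (length(n) < 2) stop("need at least two populated levels", call. = FALSE)
  s <- seq_along(n)
  N <- sum(n); R <- sum(r); pbar <- R / N
  if (pbar == 0 || pbar == 1) {
    stop("trend undefined: outcome is constant", call. = FALSE)
  }
  T_ <- sum(s * (r - n * pbar))
  V <- pbar * (1 - pbar) * (sum(n * s^2) - sum(n * s)^2 / N)
  chi2 <- T_^2 / V
  list(chi2_trend = chi2,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE), df = 1)
}

#' Wilcoxon rank-sum test on ordinal level codes
#'
#' Normal-approximation two-sided rank-sum test with the standard tie
#' correction (midranks; variance shrunk by sum(t^3 - t) over tie groups).
#' No continuity correction is applied: heavy ties on a seven-point ordinal
#' scale make the half-unit correction inappropriate.
#'
#' @param levels_a,levels_b ordinal samples (ordered factors or numeric
#'   codes on a common scale).
#' @return list with `z`, `p`, `n_a`, `n_b`.
#' @export
ranksum_ordinal <- function(levels_a, levels_b) {
  a <- as.numeric(levels_a); b <- as.numeric(levels_b)
  stopifnot(length(a) >= 1, length(b) >= 1, !anyNA(a), !anyNA(b))
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  rk <- rank(c(a, b))              # midranks
  W <- sum(rk[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(c(a, b))
  tie_adj <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_adj / (N * (N - 1)))
  if (sigma2 <= 0) {
    # all observations tied: no evidence either way
    return(list(z = 0, p = 1, n_a = n1, n_b = n2))
  }
  z <- (W - mu) / sqrt(sigma2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), n_a = n1, n_b = n2)
}
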