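test_that("confusion metrics by direct enumeration", {
  # cases at r = 2, 3; controls at r = 0, 1, 1, 3; cutoff 2
  r <- c(2, 3, 0, 1, 1, 3)
  y <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  row <- confusion_at_cutoff(r, y, 2)
  expect_identical(c(row$tp, row$fn, row$fp, row$tn), c(2L, 0L, 1L, 3L))
  expect_equal(row$sensitivity, 1.0)
  expect_equal(row$specificity, 0.75)
  expect_equal(row$youden, 0.75)
  expect_equal(row$ppv, 2 / 3)
  expect_equal(row$npv, 1.0)

  # perfectly separated data at a separating cutoff
  sep <- confusion_at_cutoff(c(5, 6, 1, 2), c(1, 1, 0, 0), 4)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  expect_equal(sep$youden, 1)

  # undefined PPV reported as NA, not 0
  none_pos <- confusion_at_cutoff(c(1, 2), c(TRUE, FALSE), 10)
  expect_true(is.na(none_pos$ppv))

  expect_error(confusion_at_cutoff(c(1, 2), c(TRUE, TRUE), 1), "control")
  expect_equal(youden_index(0.818, 0.470), 0.288)
})

test_that("cutpoint table: one row per cutoff, degenerate inputs", {
  r <- c(2, 3, 0, 1, 1, 3)
  y <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  tb <- cutpoint_table(r, y, c(1, 2, 3))
  expect_identical(nrow(tb), 3L)
  expect_equal(tb[2, ], confusion_at_cutoff(r, y, 2), ignore_attr = TRUE)
  expect_identical(nrow(cutpoint_table(r, y, numeric(0))), 0L)
  # default grid comes from the score model
  model <- default_score_model()
  tb2 <- cutpoint_table(r, y, model = model)
  expect_equal(tb2$cutoff_r, achievable_cutoffs(model))
  expect_error(cutpoint_table(r, y), "score model")
})

test_that("sensitivity falls and specificity rises with the cutoff", {
  set.seed(20)
  for (rep in 1:5) {
    r <- round(stats::rexp(300), 1)
    y <- stats::runif(300) < stats::plogis(r - 1)
    y[1] <- TRUE; y[2] <- FALSE
    tb <- cutpoint_table(r, y, sort(unique(r)))
    expect_true(all(diff(tb$sensitivity) <= 1e-12))
    expect_true(all(diff(tb$specificity) >= -1e-12))
    expect_equal(tb$youden, tb$sensitivity + tb$specificity - 1)
  }
})

test_that("optimal cutoff maximises Youden, ties break to the larger cutoff", {
  tb <- data.frame(cutoff_r = c(1.58, 1.80), youden = c(0.287, 0.288))
  expect_equal(optimal_cutoff(tb)$cutoff_r, 1.80)
  tie <- data.frame(cutoff_r = c(1, 2), youden = c(0.3, 0.3))
  expect_equal(optimal_cutoff(tie)$cutoff_r, 2)
  one <- data.frame(cutoff_r = 5, youden = 0.1)
  expect_equal(optimal_cutoff(one), one)
})

test_that("AUC equals the brute-force pair count, with ties at one half", {
  # oracle: direct enumeration over the 6 case-control pairs
  cases <- c(2, 3); controls <- c(1, 2, 4)
  s <- 0
  for (x in cases) for (y_ in controls) s <- s + (x > y_) + 0.5 * (x == y_)
  oracle <- s / 6
  res <- roc_auc(c(cases, controls), c(1, 1, 0, 0, 0))
  expect_equal(res$auc, oracle, tolerance = 1e-12)
  expect_equal(oracle, 3.5 / 6)

  # separated and identical distributions
  expect_equal(roc_auc(c(10, 9, 1, 2), c(1, 1, 0, 0))$auc, 1.0)
  set.seed(21)
  v <- stats::rnorm(4000)
  y <- rep(c(TRUE, FALSE), 2000)
  expect_lt(abs(roc_auc(v, y)$auc - 0.5), 0.03)

  expect_error(roc_auc(c(1, 2), c(FALSE, FALSE)), "case")
})

test_that("AUC two-route equivalence: Mann-Whitney vs trapezoidal ROC area", {
  set.seed(22)
  for (rep in 1:5) {
    r <- sample(0:10, 400, replace = TRUE)  # heavy ties
    y <- stats::runif(400) < stats::plogis((r - 5) / 2)
    y[1] <- TRUE; y[2] <- FALSE
    curve <- roc_curve(r, y)
    o <- order(curve$fpr)
    fpr <- curve$fpr[o]; tpr <- curve$tpr[o]
    trap <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    expect_equal(roc_auc(r, y)$auc, trap, tolerance = 1e-10)
  }
})

test_that("DeLong variance matches an explicit structural-component oracle", {
  set.seed(23)
  r <- c(stats::rnorm(40, 1), stats::rnorm(60))
  y <- rep(c(TRUE, FALSE), c(40, 60))
  res <- roc_auc(r, y)
  cases <- r[y]; controls <- r[!y]
  psi <- outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(res$auc, mean(psi), tolerance = 1e-12)
  v10 <- rowMeans(psi); v01 <- colMeans(psi)
  expect_equal(res$var_auc,
               stats::var(v10) / length(cases) + stats::var(v01) / length(controls),
               tolerance = 1e-12)
  expect_true(res$ci_low <= res$auc && res$auc <= res$ci_high)
})

test_that("AUC comparison: identical groups give p = 1, separation rejects", {
  r <- c(5, 4, 3, 1, 2, 0); y <- c(1, 1, 1, 0, 0, 0)
  same <- compare_auc(r, y, r, y)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  set.seed(24)
  a_r <- c(stats::rnorm(50, 3), stats::rnorm(50))       # near-perfect AUC
  a_y <- rep(c(1, 0), each = 50)
  b_r <- stats::rnorm(100)                              # AUC ~ 0.5
  cmp <- compare_auc(a_r, a_y, b_r, a_y)
  expect_lt(cmp$p, 0.05)
})

test_that("AUC comparison holds its type-I error under equal AUCs", {
  set.seed(25)
  reps <- 400
  rej <- 0
  for (i in seq_len(reps)) {
    y <- rep(c(1, 0), c(20, 40))
    a <- c(stats::rnorm(20, 0.8), stats::rnorm(40))
    b <- c(stats::rnorm(20, 0.8), stats::rnorm(40))
    if (compare_auc(a, y, b, y)$p < 0.05) rej <- rej + 1
  }
  # binomial 99% band around 0.05 for 400 reps: ~ (0.022, 0.078)
  expect_gt(rej / reps, 0.02)
  expect_lt(rej / reps, 0.09)
})

test_that("trend chi-square: flat, 2-level Pearson identity, oracle value", {
  flat <- trend_chi2(c(100, 100, 100), c(7, 7, 7))
  expect_lt(flat$chi2_trend, 1e-20)

  # two levels: equals the uncorrected Pearson chi-square of the 2x2 table
  tr2 <- trend_chi2(c(120, 80), c(30, 10))
  pear <- crude_chi2(two_by_two(10, 70, 30, 90))
  expect_equal(tr2$chi2_trend, pear$chi2, tolerance = 1e-10)

  # independent oracle: stats::prop.trend.test with equally spaced scores
  tt <- stats::prop.trend.test(c(1, 5, 20), c(100, 100, 100), score = 1:3)
  res <- trend_chi2(c(100, 100, 100), c(1, 5, 20))
  expect_equal(res$chi2_trend, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p, unname(tt$p.value), tolerance = 1e-10)

  # zero-enrolment levels are dropped
  with0 <- trend_chi2(c(100, 0, 100, 100), c(1, 0, 5, 20))
  expect_equal(with0$chi2_trend, res$chi2_trend, tolerance = 1e-12)

  expect_error(trend_chi2(c(100), c(5)), "two populated")
  expect_error(trend_chi2(c(50, 50), c(0, 0)), "constant")
})

test_that("rank-sum test: identity, separation, exact permutation oracle", {
  expect_equal(ranksum_ordinal(c(1, 2, 3), c(1, 2, 3))$z, 0)

  sep <- ranksum_ordinal(c(1, 1, 1, 2), c(5, 5, 6, 7))
  expect_lt(sep$z, -2)  # all of A below all of B

  # exact enumeration oracle for the tie-corrected moments, n <= 8:
  # the normal approximation uses the exact permutation mean and variance
  # of the rank sum, so both are checked by exhausting all assignments.
  a <- c(1, 2, 2, 4); b <- c(2, 3, 4, 4)
  pooled <- c(a, b)
  rk <- rank(pooled)
  combos <- utils::combn(8, 4)
  sums <- apply(combos, 2, function(ix) sum(rk[ix]))
  res <- ranksum_ordinal(a, b)
  W <- sum(rk[1:4])
  exact_mu <- mean(sums)
  exact_var <- mean((sums - exact_mu)^2)  # population variance over assignments
  expect_equal(res$z, (W - exact_mu) / sqrt(exact_var), tolerance = 1e-10)
  # and the two-sided normal p agrees with the exact permutation p within
  # the tail-approximation error expected at n = 4 + 4 with heavy ties
  exact_p <- mean(abs(sums - exact_mu) >= abs(W - exact_mu) - 1e-12)
  expect_lt(abs(res$p - exact_p), 0.2)

  # agreement with wilcox.test's tie-corrected normal approximation
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(res$p, wt$p.value, tolerance = 1e-10)

  # all observations tied
  tied <- ranksum_ordinal(c(2, 2), c(2, 2, 2))
  expect_equal(tied$z, 0)
  expect_equal(tied$p, 1)
})
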