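---
title: "Methods: building and validating the CVD risk index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating the CVD risk index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdrisk)
```

This vignette documents the model behind `cvdrisk`, the assumptions it
makes, the numerical and design choices that were genuinely open, and what
the synthetic-data tests do and do not establish.

## 1. The outcome model: Poisson regression on a binary prevalence

The outcome is a single binary indicator of prevalent cerebrovascular
disease in a cross-sectional community survey of residents aged 40 and
above. Because the prevalence is low (~4.5%), the adjusted association
model is a **log-link Poisson regression** on the 0/1 outcome:

$$\log E[Y \mid x] = \beta_0 + \textstyle\sum_f \beta_f x_f,$$

with six binary factors: age ≥ 60, lack of exercise, hypertension,
diabetes, smoking, family history of CVD. With a log link on a binary
outcome, $e^{\beta_f}$ is a *prevalence (risk) ratio*; the source
methodology labels these OR and the package keeps that column name.
Assumptions worth keeping in mind:

* the Poisson variance ($\mu$) overstates the Bernoulli variance
  ($\mu(1-\mu)$), so the default model-based standard errors are mildly
  conservative. A sandwich (`robust = TRUE`) option exists but is off by
  default, matching a plain Poisson fit;
* 95% CIs are large-sample Wald intervals $\exp(\beta \pm 1.96\,se)$
  (normal, not t, quantile);
* the linear predictor is not constrained below 0 on the log scale, so
  $e^{\hat\eta}$ can exceed 1 for extreme covariate patterns — a known
  artefact of log-link risk models (see §3 on capping).

The fit is iteratively reweighted least squares with convergence declared
when the relative log-likelihood change falls below $10^{-10}$ (or 100
iterations). Two failure modes are made explicit rather than silent:
rank-deficient designs abort naming the collinear columns, and a
coefficient drifting beyond $|\log \text{risk}| = 20$ is treated as
separation (the MLE lies at infinity) and returned as a *non-converged*
result. The second rule was added because the likelihood-change criterion
alone "converges" numerically while the intercept runs to $-\infty$ when a
stratum has zero cases.

## 2. The risk index

Given the fitted ORs, the index follows the Harvard-index recipe:

1. **Banding.** Each OR is converted into an integer risk score by the
   conversion standard. The published band edges are printed to one
   decimal (0.9~1.1 → 0, 1.1~1.4 → 5, 1.5~2.9 → 10, 3.0~6.9 → 25,
   ≥ 7.0 → 50, mirrored with negative scores on the protective side),
   which literally read leaves gaps such as (1.4, 1.5). The package
   implements the bands as **contiguous half-open intervals**
   $[0.9,1.1) \to 0$, $[1.1,1.5) \to 5$, $[1.5,3.0) \to 10$,
   $[3.0,7.0) \to 25$, $[7.0,\infty) \to 50$ (and mirrored protective
   bands down to $(0,0.2) \to -50$): the printed bounds are one-decimal
   renderings of contiguous ranges, and every shipped OR lands in the same
   band under either reading. Protective (negative) scores never occur in
   the shipped six-factor model, so that part of the surface is exercised
   only by tests.
2. **AROP.** With reference-population exposure rates $ER_f$,
   $\mathrm{AROP} = \sum_f ER_f \cdot RC_f$. The shipped registry
   reproduces the published value 22.20 exactly
   ($0.17{\cdot}25 + 0.82{\cdot}10 + 0.28{\cdot}10 + 0.11{\cdot}25 +
   0.28{\cdot}10 + 0.14{\cdot}10$). One registry entry is a *documented
   inconsistency*: the physical-exercise exposure rate ships as 0.82, the
   proportion who exercise **regularly**, although the scored factor is
   **lack** of exercise. 22.20 is only reproducible with 0.82, so the
   published registry is kept as-is rather than silently corrected;
   substituting 0.18 would lower AROP to 15.80 and rescale every R.
3. **RCI and R.** $RCI = \sum_{f \in \text{carried}} RC_f$ and
   $R = RCI/\mathrm{AROP}$. R is kept unrounded internally; reports render
   it to 2 decimals.
4. **Levels.** The published seven-level table leaves all boundaries open
   (and $R = 0$ unassigned). Classification must be total, so the package
   uses lower-closed intervals — very_low $R \le 0$; lower $(0, 0.5)$; low
   $[0.5, 0.9)$; moderate $[0.9, 1.1)$; high $[1.1, 2.0)$; higher
   $[2.0, 5.0)$; very_high $R \ge 5.0$. Assigning $R = 0$ to "very low" is
   forced by the data structure: all six scores are positive, so the
   populated very-low stratum in the published level table can only be the
   zero-score individuals.

Under the shipped model the set of achievable positive $R$ values (all
$2^6$ factor subsets) is, to two decimals: 0.45, 0.90, 1.13, 1.35, 1.58,
1.80, 2.03, 2.25, 2.48, 2.70, **2.93**, 3.15, **3.60**, **4.05**. The
published cut-off table lists eleven of these, omitting 2.93 and everything
above 3.15; the enumeration is authoritative here and the three bold values
are part of the package's default grid. The discrepancy is asserted
explicitly in the acceptance suite rather than hidden.

## 3. The synthetic cohort: the stated world

No participant data are distributed, so the generator emulates the study's
*statistical structure* and everything downstream is tested against it:

* **Marginals** default to the full-sample factor prevalences (age ≥ 60
  0.727, lack of exercise 0.182, smoking 0.150, hypertension 0.553,
  diabetes 0.143, family history 0.141, plus descriptive covariates);
  the two study halves were split at random, so pooling is appropriate.
* **Outcome** is Bernoulli with $p = \min(e^{\beta_0 + \sum \beta_f x_f},
  p_{\text{cap}})$, using the published coefficients (intercept −5.405;
  β 1.189, 0.836, 0.667, 0.920, 1.161, 0.839). The cap is needed because
  the all-factor pattern has linear predictor 0.207, i.e. a "risk" of
  1.23: the log-link model is not a probability at the extremes.
  $p_{\text{cap}} = 0.999$ (rather than 1.0) keeps the capped cells
  strictly inside the parameter space; capped draws are counted, warned
  about, and reported. Under the defaults only the all-six-factor pattern
  caps (~2 expected individuals per 10,000).
* **Dependence.** Factors are independent by default — the study reports
  no joint distribution to match. A Gaussian-copula latent correlation
  option exists because real risk factors co-occur (hypertension and
  diabetes especially), but no default correlation is asserted.
* **Split.** The modeling/validation split is the deterministic
  odd/even-enrolment-order partition; 2138 records give 1069 + 1069.

The generator emits coded profiles directly; the raw-record coding layer is
tested on hand-built records instead, because simulating realistic
continuous lab values would add free parameters the study does not pin
down.

**What a green test establishes — and what it does not.** Parameter
recovery (each generating OR inside the fitted 95% CI at n = 200,000) shows
the estimation machinery is correct *under the stated world*. It does not
validate the index against real, correlated risk factors. Concretely: the
exact population AUC of the stated world — computable by enumerating the 64
covariate patterns — is **0.744**, while the study reports 0.686 on real
data. Independence makes high-score patterns rarer among controls than they
are in reality, inflating discrimination; the seed-stability acceptance
check is therefore anchored on the exact enumeration value (median of 15
seeds within ±0.03 of 0.744), with the published 0.686 treated as a
plausibility anchor only, exactly as scoped.

## 4. Validation machinery: numerical choices

* **Cut-point convention.** Test-positive means $R \ge$ cut-off. Under the
  achievable-R grid this makes each grid value its own operating point,
  matching the published table semantics.
* **Youden ties** break toward the *larger* cut-off (higher specificity);
  degenerate predictive values (zero denominators) are `NA`, never 0.
* **AUC** is the Mann–Whitney statistic with ties counted ½; its variance
  and 95% CI use the DeLong structural components ($S_{10}/m + S_{01}/n$),
  clipped to [0,1]. The two-sample comparison is the unpaired DeLong
  z-test; a stratified bootstrap was considered and rejected as the default
  because DeLong is deterministic, standard and fast at these sizes.
* **Trend test** is Cochran–Armitage with equally spaced integer scores
  over the supplied ordered levels (zero-enrolment levels dropped); with
  two levels it reduces algebraically to the uncorrected Pearson χ², which
  the tests verify numerically. The published trend statistics are not
  reproduced: their printed stratum counts do not sum to the stated group
  sizes, so the operation is validated against `stats::prop.trend.test`
  instead.
* **Rank-sum test** uses midranks and the exact tie-corrected permutation
  variance $\frac{n_1 n_2}{12}\left[(N+1) - \frac{\sum (t^3-t)}{N(N-1)}\right]$;
  no continuity correction, because on a seven-point ordinal scale with
  heavy ties the half-unit correction is inappropriate. With every
  observation tied, z is defined as 0 (no evidence either way).
* **Two OR sets.** The methodology prints different ORs for the same six
  factors in its regression table and its score table (e.g. age 3.284 vs
  3.171) without explanation. Both are shipped, labelled `full_sample` and
  `modeling_group`; the default score model uses the `modeling_group` set,
  the only one that reproduces AROP 22.20. The pipeline, by default,
  instead *refits* the Poisson model on its own modeling half
  (`use_fitted_ors = TRUE`), which is the procedure the methodology
  actually describes; reference-OR scoring is available via
  `use_fitted_ors = FALSE`.

## 5. Known limitations

* The index is a relative measure; nothing calibrates R to absolute risk.
* The generator's independence default understates factor co-occurrence;
  AUC-level quantities from default synthetic cohorts are optimistic by
  roughly 0.05–0.06 (see §3).
* The drinking definition in the source criteria (daily consumption for a
  year) and its three-level frequency scale are reconciled by carrying both
  a boolean and the enum; drinking is descriptive only and never scored.
* Stroke subtypes and transient ischemic attacks are out of scope: the
  outcome is one binary CVD indicator.
* Units are fixed (mmol/L, mmHg, m, kg); mg/dL inputs are not accepted.
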