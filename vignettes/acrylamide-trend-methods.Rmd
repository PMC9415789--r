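---
title: "Harmonizing European acrylamide biomonitoring data and modelling its time trend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing European acrylamide biomonitoring data and modelling its time trend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrytrend)
```

## The problem

Human biomonitoring studies of acrylamide exposure report their results in
incompatible ways. Urinary studies measure the mercapturic-acid metabolites
AAMA and GAMA (µg/L in spot or morning urine, sometimes µg/g creatinine or
nmol/day in timed collections); blood studies measure the hemoglobin adducts
AAVal and GAVal (pmol/g Hb). Some publications report arithmetic means,
others only medians with a range or quartiles. Study populations differ in
size (6 to over 850 participants), mean age, sex composition, smoking
stratification, and the calendar window over which samples were collected.

To ask whether population exposure has changed over two decades, these
heterogeneous study-level summaries must first be *harmonized* onto a single
scale — one arithmetic mean in µg/L of urinary metabolite per study, year
and smoking stratum — and the resulting yearly-mean panel must then be
modelled with the study sizes taken into account. This package implements
that pipeline end to end, together with synthetic generators for every
input, so each stage can be validated without access to external data.

## Harmonization

### Means and SDs from order statistics

When a study reports only a median `m` with the range `[a, b]` or the
quartiles `q1, q3`, the arithmetic mean is approximated by the
order-statistic estimators

$$\bar X_1 \approx \frac{a + 2m + b}{4}, \qquad
  \bar X_2 \approx \frac{q_1 + m + q_3}{3},$$

and the standard deviation by the size-dependent rule

$$S \approx \begin{cases}
  \sqrt{\tfrac{1}{12}\left(\tfrac{(a - 2m + b)^2}{4} + (b-a)^2\right)} & n \le 15,\\
  (b - a)/4 & 15 < n \le 70,\\
  (b - a)/6 & n > 70.
\end{cases}$$

Both mean estimators are affine-equivariant and exact for degenerate and
symmetric inputs; the test suite verifies this by property loops. Two
behaviours matter in practice and are documented by Monte-Carlo tests
rather than assumed:

* For symmetric data, the range estimator is unbiased.
* For right-skewed (log-normal) data at large `n`, the *range* estimator
  overestimates the mean substantially — the sample extremes of 91 skewed
  draws sit far into the tail — while the *quartile* estimator stays close
  to the truth with an order of magnitude less variance. For this reason,
  when a record carries both quartiles and a range, `harmonize()` prefers
  the quartile form. Means derived from a range at large `n` should be
  read as upper-leaning estimates.

A published range of the form "LOD–x", where the numeric detection limit is
not given, cannot be used directly. We close the interval at zero (the most
conservative non-negative lower bound), derive the mean, and flag the
record `low_confidence`. This convention is a deliberate repo decision: the
one published computation of this kind is not reproducible from its printed
inputs for *any* non-negative detection limit, so we prefer a transparent
rule plus a flag over matching an unreproducible number.

### Trans-matrix conversion (blood → urine)

Blood adducts and urinary metabolites both track the underlying acrylamide
intake. In individuals with approximately constant exposure — typically
smokers — simultaneously sampled blood and urine levels are proportional,
and under a hypothetical zero-exposure scenario both biomarkers vanish, so
the calibration line is forced through the origin:

$$\text{AAMA}_{\mu g/L} \approx k \cdot \text{AAVal}_{pmol/g},\qquad
  \hat k = \frac{\sum_i u_i b_i}{\sum_i b_i^2},$$

the zero-intercept least-squares slope, with its standard error and
no-intercept $R^2$ from the same model. The routine two-decimal factors are
1.64 for the acrylamide pair and 0.35 for the glycidamide pair
(`fixed_conversion_factors()`); `fit_conversion_factor()` derives a factor
from any paired dual-matrix dataset. The factor is fitted on all paired
records regardless of smoking status: constant exposure is needed for the
*calibration* sample, not for the populations the factor is later applied
to, because trend analysis works on yearly means and the few-weeks lag
between the two matrices never moves a sample across years.

The glycidamide conversion is implemented but **off by default** in
harmonization: GAMA formation depends on CYP2E1 activity, which varies
regionally, so a GAVal→GAMA factor is only valid within the population it
was fitted in and must be supplied deliberately
(`harmonization_rules(apply_gama_trans_matrix = TRUE)`).

Worked check (computed by the test suite): a smokers' blood median of
79.1 pmol/g Hb converts to `1.64 × 79.1 = 129.7` ng/mL, a non-smokers'
26.8 pmol/g Hb to 43.95 ng/mL, and a blood mean of 36 pmol/g Hb (itself
derived from median 30, range 15–71) to 59.04 µg/L — an error of −8.5%
against the corresponding measured urinary mean of 64.5 µg/L.

### Inclusion rules and year assignment

`harmonize()` applies, in order (each dropped record is logged with its
rule number):

1. drop records not stratified by smoking status — smokers and non-smokers
   differ several-fold in exposure, so mixed means are not comparable;
2. drop records with fewer than `min_n = 6` participants (the conventional
   minimum for validating a mean from an analytical study);
3. drop records with no assignable sampling year;
4. drop matrix/unit combinations that are not comparable on the µg/L
   scale: 24 h and 12 h urine collections (systematically more dilute than
   spot samples), creatinine- and per-day-based units, blood not in
   pmol/g Hb, and glycidamide blood records unless a factor is supplied;
5. assign the midpoint of a multi-year sampling window as the record's
   decimal year (flagged `multi_year`; a three-year window therefore
   carries at most ±1 year of dating error);
6. estimate missing means from quartiles, else from median and range;
7. convert blood means to urinary equivalents;
8. drop records the source tables themselves flag as excluded (e.g.
   overlap with an aligned survey).

The panel row that comes out carries a `provenance` code
(`measured_mean`, `mean_from_quartiles`, `mean_from_median_range`,
`trans_matrix`, `trans_matrix_plus_median`) so every harmonized value is
traceable to the estimators that produced it.

One open design point: when a study reports *both* a urinary record and a
blood record for the same year (one published dual-matrix study does), both
harmonized rows are kept. No published de-duplication rule exists, the two
rows are genuinely different measurements of the same population, and the
study-size weighting treats them consistently. With this choice the
packaged fixtures reconstruct a non-smoker AAMA panel of 30 yearly means —
the analysis-set size the source analysis reports — although the published
sample totals cannot be matched exactly from the printed tables alone; the
reproduction recipe logs its own counts instead of asserting published
totals.

`harmonize()` is permutation-invariant and idempotent: re-harmonizing an
already-harmonized panel (via `as_study_records()`) changes no mean, year
or count — though provenance necessarily collapses to `measured_mean`,
since the re-imported records now carry explicit means.

## Trend models

All three models weight each yearly mean by its study size `n`. The
generator and the weighting assumption agree by construction: study-level
noise scales as $1/\sqrt{n}$, so weighting by `n` is the efficient choice.
Weights are used unnormalized; all fits are invariant to rescaling them.

### Weighted multiple regression

`fit_weighted_mlr()` minimizes $\sum_i w_i (y_i - x_i'\beta)^2$ via QR on
the $\sqrt{w}$-scaled design. Covariates are coded on their natural scales
— calendar year (uncentered, so the slope is µg/L per calendar year), mean
age in years, percent male 0–100 — and records missing a covariate are
dropped with a log entry. Standard errors come from the weighted
information matrix with $\hat\sigma^2 = \text{SSE}_w/\text{df}$, and
p-values from a two-sided Student t on `n_obs − n_params` df (the source
analysis does not state its inference machinery; this is the conventional
choice). The implementation is verified three ways: against R's own
`lm(weights =)`, against a brute-force BFGS minimizer of the weighted SSE
(agreement to 1e−8), and by parameter recovery on generated panels.

### LOESS

`fit_loess()` is a from-scratch local polynomial smoother: at each grid
point the `ceiling(span · n)` nearest years get tricube kernel weights,
multiplied by the study-size prior weights, and a local polynomial is
solved by weighted least squares centered at the evaluation point.
Defaults are span 0.75, degree 2, 0 robustness iterations — the
conventional defaults of the method. Centering makes the curve exactly
invariant to shifting the time axis, and the smoother reproduces any
global polynomial of its own degree to numerical precision (both are
tested). Pointwise standard errors use the local smoother vector with the
global weighted residual variance — adequate for the confidence ribbon the
curve is exported for, not for formal inference.

### Segmented (breakpoint) regression

`fit_segmented()` fits $y = \beta_0 + \beta_1 t + \beta_2 (t-\psi)_+$ by
iterative linearization: the design is augmented with $U = (t-\psi)_+$ and
$V = -\mathbf 1[t > \psi]$, and each iteration moves the breakpoint by
$\hat\gamma/\hat\beta_2$ until the gap $|\hat\gamma| < 10^{-6}$ (at most
100 iterations). The weighted-SSE profile in $\psi$ is piecewise smooth
with kinks at the observation years, so the iteration can stall in a local
valley; the fit therefore always cross-checks against a grid search at
0.05-year resolution over the interior of the year range and restarts from
the grid optimum if that improves the SSE. `slope_left` is $\beta_1$,
`slope_right` is $\beta_1 + \beta_2$; `se_psi` comes from the delta method
on the $V$ coefficient at convergence. The default segmented model is
univariate in year (the published breakpoint figure shows a univariate
trend); covariates can be added through the `covariates` argument.

### Does a breakpoint exist at all?

Since $\psi$ is unidentified under the straight-line null, the classical F
test does not apply; `test_breakpoint()` uses a parametric bootstrap. The
observed statistic

$$F = \frac{(\text{SSE}_{lin} - \text{SSE}_{seg})/2}{\text{SSE}_{seg}/\text{df}}$$

charges the segmented model its two extra parameters. `n_boot` response
vectors are simulated from the fitted weighted linear model (normal errors,
variance MSE$/w_i$), the segmented model is re-minimized on each (same
iterative-plus-grid strategy, so observed and bootstrap statistics are
exchangeable), and
$p = (1 + \#\{F^\ast \ge F\})/(n_\text{boot} + 1)$ — which floors the
p-value at $1/(n_\text{boot}+1)$. The suite checks size (rejection rate
within [0.5%, 15%] at $\alpha = 0.05$ over 50 null panels, 199 replicates
each) and power (a rise of +2.1 µg/L/yr breaking to a decline in 2017 is
rejected at $p \le 0.01$ with 499 replicates). Davies' test and
multiple-breakpoint search are out of scope.

## Synthetic data: what it emulates, what it does not

`gen_dual_matrix()` draws blood levels log-normally per smoking stratum
(non-smokers near 27 pmol/g Hb, smokers near 80, ~40% log-scale spread —
the magnitudes seen in published dual-matrix populations) and sets urine
to `slope × blood × exp(ε)` with a 20% multiplicative CV by default.
`gen_individual_study()` summarizes log-normal samples as order statistics
for estimator validation. `gen_panel()` produces yearly study means around
a (broken-)linear trend: defaults are years 2001–2020, 40 µg/L at the
reference year, +2.1 µg/L/yr rising to a 2017 breakpoint then −1 µg/L/yr,
an age effect of −0.5 µg/L per year of age, no sex effect, study sizes
20–400 and 8 µg/L of between-study spread at n = 100. Log-normality was
chosen because biomarker concentrations are non-negative and right-skewed
— precisely the setting the order-statistic estimators exist for.

What the generators deliberately do **not** model: urine-density/creatinine
dynamics, regional CYP2E1 structure (beyond leaving the GAMA conversion
off), correlation between records from the same country or laboratory,
measurement-method drift over calendar time, and non-normal residual
tails. Passing the synthetic recovery tests therefore shows the estimators
and optimizers are correct under the model's own assumptions — it does not
certify those assumptions for real panels, where the residual diagnostics
(`export_residual_diagnostics()`) should be inspected.

Generators are seeded (Mersenne-Twister, R's default) through a helper
that restores the caller's RNG state, so identical seeds give identical
records and no generator call disturbs the surrounding analysis stream.

## Numerical choices and degenerate inputs

* Breakpoint iteration tolerance $10^{-6}$ on the gap; grid resolution
  0.05 years (tests compare against an independent 0.01-year grid).
* Quartile estimator preferred over the range estimator when both are
  available (lower variance, less skew-bias).
* Estimator preconditions (`a ≤ m ≤ b`, `q1 ≤ m ≤ q3`, positive reference
  in relative errors, non-negative blood levels) raise classed domain
  errors instead of returning nonsense.
* Degenerate point-mass inputs (`a = m = b`) return the point and SD 0.
* A rank-deficient trend design (e.g. a constant covariate) raises a
  collinearity error naming the column.
* Empty harmonization input yields an empty panel plus a complete
  exclusion log, not an error.
* Absent CSV cells are `NA` in memory and empty cells on disk; `0` is
  always a real measurement.

## Problem sizes used by the shipped checks

The test suite and the acceptance script size their simulations to run
comfortably on one CPU: 1,000-replicate Monte-Carlo loops for estimator
bias, 50 null panels × 199 bootstrap replicates for the size of the
breakpoint test, 499 replicates for its power, and 24-subject dual-matrix
scenarios for factor recovery. These are the package's own choices of
problem size and are stated in the tests themselves.

## Known limitations

* Trend weights are study sizes only; no between-study variance component
  is estimated (no meta-regression with heterogeneity), and estimator
  variance from the harmonization step is not propagated into the weights.
* The range-based mean estimator is upward-biased for skewed data at large
  `n` (see above); affected records are identifiable via `provenance`.
* Creatinine- or density-corrected analyses are out of scope (inputs not
  available at study level).
* The smokers' trend uses the same WLS machinery as the non-smokers'; no
  GLS correlation structure is modelled.
* The exact membership of the originally published analysis set is not
  uniquely reconstructible from the printed tables; the reproduction
  recipe logs its reconstruction (30 yearly means) rather than asserting
  published sample totals.
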