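---
title: "Identifying incident dementia from administrative claims: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying incident dementia from administrative claims: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrdrisk)
library(data.table)
```

# The problem

Alzheimer's disease and related dementias (ADRD) are common, costly, and
systematically under-coded in routine health data. Administrative claims —
diagnosis codes, procedure codes and pharmacy fills generated as a
by-product of billing — are available at population scale, which makes them
attractive for finding people at elevated risk *before* a recorded
diagnosis, e.g. to enrich clinical-trial recruitment. `adrdrisk`
implements, as a tested and reusable pipeline, the full chain such a study
needs:

1. **Case phenotyping** — a rule-based ADRD outcome definition with
   confirmation windows and an incidence washout (`phenotype_population()`).
2. **Nested case-control cohort construction** — eligibility filters with
   an exclusion ledger, control index dates drawn from the case
   enrollment-duration distribution, a train/test split, and 1:5 matching
   on age, gender and enrollment duration (`build_cohort()`).
3. **Sparse binary feature engineering** from a fixed pre-index window
   (`build_feature_matrix()`).
4. **Two-phase model fitting** — cross-validated L1-penalised logistic
   selection capped at 50 predictors, then an unpenalised logistic refit
   (`fit_risk_model()`).
5. **Prevalence-threshold evaluation** — sensitivity, specificity, PPV,
   lift and rank AUC at a threshold set so the flagged fraction equals the
   case prevalence, optionally stratified by age
   (`evaluation_report()`).

Because real claims warehouses are proprietary, the package ships a seeded
synthetic claims generator (`simulate_claims()`) that emulates the
structure of such data and plants ground truth, so every stage is testable
end to end without any data access.

# The outcome definition

A member is a confirmed ADRD case if at least one of four criteria holds:

* **(a)** an ADRD diagnosis claim, any header position, in an **inpatient**
  setting;
* **(b)** two ADRD diagnosis claims, any setting, whose dates differ by
  **1 to 730 days** (inclusive at both ends — a same-day duplicate never
  confirms);
* **(c)** a pharmacy fill of an ADRD monotherapy drug (donepezil,
  galantamine, rivastigmine or tacrine);
* **(d)** a memantine fill with an ADRD diagnosis claim within **0 to 730
  days** in *either* temporal order. Memantine alone never qualifies
  because it is also prescribed outside dementia.

Two dates matter and they are deliberately different:

* the **confirmation date** is the earliest date at which some criterion is
  fully satisfied (for the pair rules b and d, the *later* member of the
  earliest satisfying pair);
* the **index date** — the disease-onset proxy from which every lookback
  window is measured — is the earliest qualifying event of *any* kind in
  the member's history, even when it precedes the confirmation by more than
  730 days.

When several criteria confirm on the same day the rule label is assigned
with precedence a > b > c > d; the precedence only breaks exact date ties
and never moves a date. `case_pattern_fixtures()` ships five hand-dated
single-member datasets, one per canonical trajectory, which double as
executable documentation of these rules and are asserted exactly in the
test suite.

**Incidence washout.** A confirmed case is *incident* only if a single
enrollment span covers the 60 calendar months ending at the index date and
no qualifying event falls inside that window before the index. Months are
calendar months with month-end clamping (60 months before 2012-02-29 is
2007-02-28), not a fixed day count. Because the index date is defined as
the earliest qualifying event the claim-freedom condition holds by
construction; it is still checked, and an inconsistency raises an error
rather than a silent reclassification.

# Cohort construction

Eligibility requires at least one enrollment span *strictly* longer than
five calendar years and no long-term-care residence flag (LTC residence is
strongly associated with pre-existing and under-coded dementia). Every
filter appends a row to an `exclusion_ledger`, whose running arithmetic
(`remaining[i] = remaining[i-1] - removed[i]`) is validated, so a published
exclusion cascade can be replayed and audited with `ledger_replay()`.

The case arm then drops, in order: members whose ADRD signal never
confirms; confirmed cases that fail the washout **or** are younger than 45
at index (one combined step, mirroring how such cascades are usually
reported); and members with no claims at all in the feature window (these
would enter the model as all-zero rows; the no-claims window is a design
choice documented here because published cascades rarely state one).

**Control index dates.** Controls have no disease anchor, so their index
dates are manufactured to remove enrollment-duration confounding: the 101
nearest-rank percentiles (0, 1, ..., 100) of the case
enrollment-to-index durations are computed, each control draws one of the
101 values uniformly at random, and its index date is its span start plus
that duration. Controls whose index lands outside their span are dropped
and counted (`outside_coverage`), then the under-45 and no-claims filters
apply. Nearest-rank (inverse empirical CDF) percentiles are used — rather
than an interpolating quantile — because the assignment draws *one of
these enrollment durations* as discrete values, and because integer-day
percentile tables include the observed minimum and maximum.

**Split and matching.** A seeded simple random sample of the cases, and
independently the same fraction of the controls, is held out for test
(fraction rounded half-up; default 0.3). Test controls are
enrollment-duration matched by construction of their index dates and are
*not* matched on age or gender — which is exactly why test-set
discrimination exceeds training-set discrimination on age-graded outcomes.
Training controls are matched 1:5 without replacement on gender, 5-year
age bin at index (ages above 89 capped at 89) and enrollment-duration
decile; cases are processed in seeded random order and keep whatever
matches are available ("up to 5"). With full matching the training
prevalence is 1/6 ≈ 16.67%.

# Features

For every cohort member the pipeline collects claims from the **fourth and
fifth years before the index date**: days 1096 to 1825 before index, both
bounds inclusive, using fixed 365-day years (leap days are ignored for
window arithmetic so the window is a deterministic 730-day block). Each
diagnosis code, ingredient-level drug name and radiology CPT code (default
range 70000–79999, configurable) becomes a binary presence indicator — 1
if at least one windowed claim carries it, regardless of multiplicity.
Demographics enter as 5-year age-bin indicators from 40–44 to 85–89 with
65–69 as the reference, plus a female indicator (male reference). The
40–44 bin is kept in the vocabulary even though cohort members are 45 or
older at index, so the demographic block has a fixed, predictable layout.

The vocabulary is built from training rows only — clinical features never
observed in training do not exist — and is then **frozen**: test-time
features outside it are dropped, never added. `sparsity_profile()`
reports, per label, the cumulative distribution of clinical codes per
member; on realistic inputs most members carry only a handful of codes,
which is the central difficulty of this classification problem.

# The two-phase model

**Phase one (selection).** An L1-penalised logistic regression is fit down
a geometric lambda grid (100 points, `lambda_min = 1e-4 * lambda_max`) with
4-fold cross-validation on binomial deviance, folds assigned by a seeded
permutation. Path traversal stops once the active set would exceed 50
predictors, so every candidate model respects the cap. Features are
standardised inside this phase only, because the penalty is
scale-sensitive. The penalised path and cross-validation are computed by
`glmnet::cv.glmnet()` (its `pmax` argument implements the active-set cap);
the package adds the fold seeding, the cap-aware model choice and the
selection rule.

*Choosing the path point.* The default rule (`rule = "cv_1se"`) takes the
sparsest model whose mean CV deviance is within one standard error of the
best, restricted to the capped path. The literal deviance argmin
(`rule = "cv_min"`, also available) is unstable here: on sparse binary
designs the CV curve is nearly flat past the true model size, with
between-point differences two to three orders of magnitude below the CV
standard error, so the argmin lands on a noise-determined point and drags
in spurious predictors. The one-standard-error rule is the standard guard
against exactly this, and with it the selection test suite recovers all
ten planted odds-3 predictors with zero false positives at n = 20,000,
p = 510.

**Phase two (refit).** The selected variables are refit by plain
maximum-likelihood logistic regression on the raw 0/1 features (no
standardisation, no penalty), so coefficients are log-odds per code.
Convergence requires a relative log-likelihood change below 1e-8 within
100 iterations; constant columns, exact collinearity and suspected perfect
separation are hard errors, not warnings. Wald z tests come from the
Fisher information at the optimum, and each feature gets a variance
inflation factor `VIF_j = 1/(1 - R²_j)` computed via the inverse
correlation matrix (with a per-column least-squares fallback that reports
perfectly collinear columns as infinite). The intercept carries no VIF. In
an age/gender-matched training set the demographic indicators are
uninformative by design and are typically not selected; the intercept then
absorbs the matched baseline (`demographics can be forced into the refit
by selecting them explicitly in` `logistic_refit()`).

# Evaluation

Scores are the logistic inverse-link of the linear predictor. The
classification threshold is set so the flagged fraction equals the case
prevalence: with `m = ceiling(prevalence * n)` the threshold is the m-th
largest score, and the rule is *at or above*, so score ties at the
threshold are all flagged — when this inflates the flagged fraction the
function warns rather than silently re-balancing. Reported metrics are
sensitivity, specificity, PPV, and **lift** = PPV / prevalence, the fold
enrichment of true cases in the outreach list relative to random outreach.
`ppv_from_rates()` provides the Bayes identity
`PPV = s·π / (s·π + (1-c)(1-π))`, used in the tests to audit published
operating points. AUC is the rank-based (Mann–Whitney) statistic with
midrank ties, equal by construction to the all-pairs concordance
proportion.

`stratified_evaluation()` repeats the thresholding inside age strata
(default labels 15–64, 65–74, 75–99; fully configurable, e.g.
`"40-64,65-74,75-99"`), each stratum at its own prevalence, and adds a
pooled `"computed"` row whose confusion counts are the element-wise sums
of the stratum counts. Per-stratum thresholds help exactly when prevalence
is strongly age-graded while the score carries little age signal — the
regime produced by age-matched training — because the global score
ordering then misallocates outreach toward low-prevalence strata. The
test suite verifies this qualitative gain in at least 90% of 50 seeded
replicates of that regime (three strata of 2,000 members, prevalences
1%/5%/15%, score-age trend 0.3 logits per stratum).

# The synthetic claims generator

`simulate_claims()` is first-class, tested code, not a fixture. It
generates members (birth years 1920–1965, even gender mix, 3%
long-term-care flags), one continuous enrollment span each (lengths
uniform on 1,400–4,000 days, so a realistic minority fails the five-year
eligibility filter), sparse background medical and pharmacy events, and a
planted fraction of cases:

* every member draws an enrollment-to-index offset uniform on
  **1,827–2,735 days** — the range brackets a five-year washout spanning
  two leap days (1,827 days) at the low end, consistent with
  percentile-table floors observed in large claims cohorts — recorded in
  the truth sidecar as the *reference index date*;
* planted cases realise one of the five canonical trajectories at that
  index (equal mix by default), with within-pattern gaps drawn to satisfy
  or deliberately exceed the 730-day windows; spans are stretched when
  needed so the washout and the whole trajectory fit inside;
* background codes (26 common diagnoses/procedures) and drugs (8
  ingredients) occur as per-year Bernoulli events at rates 0.04–0.25,
  dated uniformly within the span. Background generation **never** emits
  ADRD codes or qualifying drugs, so planted trajectories are the only
  qualifying events: phenotyping must recover every planted case with its
  exact index date and flag no control, and the tests assert precisely
  that;
* eight planted risk codes appear in the 4th–5th pre-index-year window
  with control probability 0.05 and case probability inflated on the odds
  scale by configurable multipliers (defaults 1.5–4), giving the model a
  recoverable signal whose empirical odds ratios are themselves tested
  (within 50% relative error at n = 20,000).

The truth sidecar (labels, patterns, planted and reference index dates) is
written separately and never consumed by pipeline stages.

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about real data: code co-occurrence and comorbidity
structure (codes are independent given case status), within-member
temporal autocorrelation of utilisation, coding-practice drift over years,
gaps and churn in enrollment (one span per member), under-coding of
dementia itself, and any regional or plan-level heterogeneity. Results on
synthetic data validate the *machinery* — rule logic, ledger arithmetic,
matching, selection behaviour, threshold algebra — not real-world
discrimination, which in published large-scale claims studies sits far
below what clean planted signal produces.

# Numerical conventions, degenerate inputs, problem sizes

* Calendar arithmetic uses real Gregorian dates; month and year offsets
  clamp at month ends. "More than 5 years" of enrollment is a strict
  calendar comparison, so an exactly-five-year span is ineligible.
* Quantiles are nearest-rank everywhere (percentile table, duration
  deciles, prevalence thresholds) for internal consistency and exact
  reproducibility on integer data.
* Determinism: every stochastic step (generation, fold assignment, control
  duration draws, split, matching order) is driven by an explicit seed,
  and identical configuration yields byte-identical CSV exports.
* Degenerate inputs fail loudly: single-class labels, empty matrices,
  constant or collinear columns, prevalence outside (0,1), ages outside
  the strata, unknown exclusion rules and malformed configurations are
  all named errors.
* Default scales: the test suite and the acceptance script run the full
  pipeline at 20,000 synthetic members (about 1,000 planted cases), the
  selection properties at n = 20,000 × p = 510, parameter recovery at
  n = 50,000, and the stratified-gain replication at 50 × 6,000 scores —
  sizes chosen so each statistical property has comfortable power while a
  complete run stays in the tens of seconds on one core.

# Known limitations

* The ADRD diagnosis code list is a configurable default, not a validated
  registry instrument; production use should supply a protocol-mandated
  list through `adrd_code_set()`.
* Long-term-care residence is consumed as a precomputed flag; identifying
  it from claims is out of scope.
* ICD-10 is out of scope; the pipeline models the ICD-9 era.
* No sampling-bias weight correction is applied to the logistic refit
  after control undersampling; the intercept reflects the matched design,
  not the source-population prevalence.
* Confidence intervals for AUC, calibration assessment and decision-curve
  analysis are not implemented.
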