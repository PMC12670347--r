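---
title: "Methods: target-trial emulation and targeted learning for ICU therapies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target-trial emulation and targeted learning for ICU therapies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septrial)
```

## The question and the estimand

Observational ICU data invite a causal question that cannot ethically be
randomized: do life-sustaining therapies — invasive mechanical ventilation
(IMV) and vasopressors — reduce in-hospital mortality in septic patients,
and does the answer differ by cancer status and illness severity? septrial
implements the full analysis pipeline for this question as an emulated
target trial: the observational cohort is filtered and time-anchored the
way the hypothetical randomized trial would have been, and the average
treatment effect (ATE)

$$\psi = E[Y(1)] - E[Y(0)]$$

is estimated per treatment, overall and within cancer-category and
severity strata. On a binary outcome the ATE is a risk difference; on
28-day hospital-free days (HFD) it is a difference in days.

## Target-trial construction

Stays enter the trial if the patient is older than 18 years (strictly),
carries a sepsis flag, is on a first ICU stay, has a documented discharge
location, and stayed at least one day. The filters are applied in that
fixed order so the exclusion log is deterministic; applying them twice is
a no-op.

*Time zero* is ICU admission. Treatment assignment uses a 24-hour
eligibility window: a stay is "treated" iff the therapy began within the
first 24 h (boundary inclusive — the window is stated as "within the first
24 h" without boundary semantics, and we fixed the inclusive reading). A
stay whose therapy began after the window stays in the *control* arm and is
never dropped; this is what removes immortal time bias, because no stay
has to survive past hour 24 to qualify for either arm.

Outcomes:

* `Y_mortality` — composite in-hospital mortality: death in hospital *or*
  discharge to hospice.
* `Y_hfd` — 28-day hospital-free days. The literature leaves this
  undefined at the edge cases, so the package fixes the prevailing
  clinical-trials convention: 0 on composite mortality, otherwise
  `max(0, 28 - ceiling(LOS))`.
* `Y_parity` — the negative control: 1 if the death/discharge event fell
  on an even hour of day. No plausible mechanism lets a treatment move the
  event across the odd/even boundary, so a non-null estimate flags
  residual bias.

Cancer status is derived from diagnosis codes through a supplied mapping
table with a strict precedence: metastasized > hematological > solid >
none. A stay with both hematologic and metastatic codes is metastasized.
Unmapped codes are counted and ignored, never fatal.

Severity strata come from a predicted mortality probability (PMP),
`expit(a + b * severity_score)`. The calibration `(a, b)` is always
injected configuration: published severity scores (OASIS, APACHE) carry
proprietary-ish prediction formulas that we do not hard-code, and a silent
default would invite silent miscalibration. Strata are either empirical
tertiles (low / moderate / high) or explicit half-open probability bands
`[e_i, e_{i+1})`; estimation always adds the full-range `0%-100%` stratum.
If every PMP is identical, tertile mode collapses to a single stratum with
a warning.

Missing covariates are median-imputed with a per-variable missingness
indicator appended to the design matrix: the cohort size stays intact and
the learners can exploit informative missingness.

## Nuisance estimation: cross-validated stacking

All nuisance functions — the outcome regressions $\bar Q(a, X)$ and the
propensity score $g(X) = P(A = 1 \mid X)$ — are fit by a super learner: a
convex stack over a deliberately heterogeneous library:

| learner  | role                              | fixed settings |
|----------|-----------------------------------|----------------|
| `mean`   | constant benchmark                | — |
| `glm`    | linear main-effects model          | — |
| `glmnet` | sparse / shrunken linear model     | lasso mixing, penalty by internal CV |
| `ranger` | random forest                      | 500 trees, single thread |
| `gam`    | adaptive regression splines (mgcv) | smooth per continuous covariate, REML |

Each learner is trained on k−1 folds and predicts the held-out fold
(k = 5 by default, folds outcome-stratified under binomial loss with
overall sizes balanced within one). Weights minimize the cross-validated
risk of the weighted out-of-fold prediction over the probability simplex.
The optimizer runs a bounded quasi-Newton search over a normalized
non-negative parameterization from two starts (equal weights and the best
single learner) and keeps the best candidate among those solutions and
every vertex — so the stacked CV risk is never worse than the best single
learner's, by construction rather than by hope. A learner that fails on
any fold is dropped with weight zero and a warning; the stack never aborts
because one library member cannot cope with a small stratum.

Hyperparameters are fixed at conventional defaults on purpose: the
stacking weights, not per-learner tuning, are the adaptive element.

## Targeted maximum likelihood estimation

Given initial $\bar Q^0$ and truncated $\hat g$, the ATE is targeted in
one logistic fluctuation step:

1. clever covariate $H(A, X) = A/\hat g(X) - (1-A)/(1-\hat g(X))$;
2. logistic regression of $Y$ on $H$ with offset
   $\operatorname{logit} \bar Q^0(A, X)$ and no intercept, giving
   $\hat\varepsilon$;
3. $\bar Q^*(a, X) = \operatorname{expit}\{\operatorname{logit}\bar Q^0(a,X)
   + \hat\varepsilon H(a, X)\}$;
4. $\hat\psi = \frac1n \sum_i \bar Q^*(1, X_i) - \bar Q^*(0, X_i)$;
5. SE from the sample variance of the efficient influence curve
   $H(A,X)(Y - \bar Q^*(A,X)) + \bar Q^*(1,X) - \bar Q^*(0,X) - \hat\psi$,
   Wald 95% intervals.

Because step 2 is an MLE, the score equation
$\frac1n\sum_i H_i (Y_i - \bar Q^*(A_i, X_i)) = 0$ holds at convergence;
every fit records its residual and the tests require it below $10^{-6}$.
The counterfactual mean under a fixed arm (the "baseline mortality"
estimand) uses the single clever covariate
$\mathbf 1\{A = a\}/\hat g_a(X)$ and is otherwise identical.

Numerical choices, all configurable:

* propensity truncation to [0.025, 0.975] — the common default; the
  bounds are reported with every result and widening them can only reduce
  the number of truncated values;
* all probabilities clipped to $(10^{-6}, 1-10^{-6})$ before logits;
* continuous bounded outcomes mapped linearly to [0, 1]
  (`scale_bounded()`), fluctuated on the logistic scale, and mapped back
  to days — the standard bounded-outcome device; their initial outcome
  regression uses squared-error loss;
* a single joint $\varepsilon$ on $H_1 + H_0$ (not two-$\varepsilon$ or
  iterated targeting);
* nuisance fits are not cross-fitted across an outer split by default,
  matching common practice for this estimator at these sample sizes;
* one treatment is analyzed at a time; the other therapy keeps its
  natural, covariate-driven distribution, and since the generator draws
  the two treatments conditionally independently given covariates, the
  estimand matches the oracle's forced-arm contrast;
* degenerate strata (an empty arm, or fewer than 50 stays) are emitted as
  explicit skip records, never silently dropped.

## Allocation disparity: boosted propensity + Shapley odds ratios

Whether cancer categories receive therapy at different rates, adjusting
for everything else, is estimated without a linearity assumption: an
XGBoost classifier (depth 3, learning rate 0.3, 100 rounds, single thread)
predicts treatment from the covariates plus cancer one-hot indicators
(cancer-free stays are the reference), and tree-path Shapley attributions
on the log-odds margin are compared between stays with and without the
indicator:

$$\text{OR} = \exp\big(\overline{\phi}_{z=1} - \overline{\phi}_{z=0}\big),$$

the additive-attribution analogue of exponentiating a logistic
coefficient. An indicator the trees never split on has OR exactly 1.

Uncertainty comes from repeated resampling: in each of 100 iterations the
rows are shuffled into 5 folds; each fold (20% of the data) trains the
model and the attribution OR is evaluated on the held-out 80%; the five
fold ORs are averaged on the log scale (the coherent scale for ratios)
into an iteration OR. The point estimate is the median iteration OR. The
95% interval is the 2.5/97.5 percentile range of the *fold-level* ORs —
the interval is formed before fold averaging. This matters: iteration
means average over a full partition of the same data, so their spread
reflects only partition noise and collapses to a sliver; the fold-level
spread behaves like a subsampling bootstrap of a 20%-sample estimator and
covers the null honestly (verified in the acceptance tests). A
`invert_split` switch provides the conventional cross-validation reading
(train on 80%, attribute on the held-out fold) for sensitivity.

## Diagnostics

`positivity_table()` cross-tabulates treated/control counts for every
treatment × cancer category × severity stratum and flags empty arms;
stratified estimation consults it and converts empty-arm strata into skip
records. `negative_control()` reruns the full TMLE with `Y_parity` as the
outcome; a CI excluding zero is reported, never fatal — it is evidence
about the analysis, not a gate.

## The synthetic cohort and its oracle

The generator (`dgp_config()` / `generate_cohort()`) emulates exactly the
statistical structure the analysis assumes: seven first-24h covariate
aggregates; a latent cancer category with diagnosis-code lists that the
code-based categorizer must recover exactly; per-treatment logistic
propensities on standardized covariates and cancer indicators; an
initiation-hour law (gamma, median ≈ 10 h, ~17% of starts beyond 24 h) so
the eligibility window does real work downstream; a logistic composite
mortality model with a positive treatment-by-severity interaction; a
truncated log-normal length of stay; an event hour drawn independently of
everything (the negative control is null *by construction*); and explicit
contamination fractions (minors, repeat stays, missing discharge, sub-day
stays, missing sepsis flag) so the inclusion filters are exercised with
computable expectations.

No public ICU database documents its covariate joint distribution, so the
default parameter values are invented. They were chosen once, before any
estimator ran, to land near familiar margins of a pooled US septic ICU
cohort — roughly 10% cancer prevalence (solid/hematological/metastasized
≈ 4/2.4/4%), overall composite mortality in the mid-teens with roughly
double that among cancer stays, 40–50% of stays treated within the
window, median length of stay near five days — and with the severity score
deliberately driving both treatment and outcome, so the naive
treated-vs-control contrast is confounded by ≥ 3 percentage points while
the true ATEs sit near +4–5 points. The severity coefficients also imply
the PMP calibration (`default_calibration()`), which is how the
stratification gets a common ground truth.

`compute_truth()` is the brute-force oracle: it simulates the structural
equations at $n_{mc} \ge 10^4$ covariate draws with the treatment of
interest forced on/off, Rao-Blackwellising the mortality contrast
(conditional probability differences) and coupling the death and
length-of-stay draws for the HFD contrast, and reports Monte-Carlo
standard errors as sd$/\sqrt{n_{mc}}$. For single-binary-confounder
configurations the oracle is checked against the closed-form standardized
risk difference.

What the generator does *not* emulate — and therefore what passing tests
cannot show about real data: no event-level time series (first-24h
aggregates are drawn directly), no informative missingness mechanism, no
care-withdrawal dynamics linking code status to outcomes, no
between-hospital heterogeneity, and length of stay independent of
treatment given survival (so the designed HFD effect flows through
mortality only). Passing the suite demonstrates that the estimators
recover known truths under the assumed structure; it cannot certify
ignorability in any real cohort.

## Validation problem sizes

The acceptance suite runs, with fixed seeds: oracle truths at
$n_{mc} = 10^5$; TMLE recovery as the mean over 100 generator seeds at
n = 20,000 (naive contrast reported alongside); CI coverage over 200
replicates at n = 2,000; the g-formula equivalence on a randomized
single-confounder design at n = 2,000; disparity-OR calibration at
n = 10,000 against a logistic truth of 2.0 plus ten null-data runs; and
100 negative-control cohorts at n = 4,000. TMLE experiments use the
{mean, glm} stack — the synthetic propensity and outcome are essentially
logistic-linear, so the linear learner is well-specified there and double
robustness covers the remainder; the full five-learner library is
exercised separately for the stacking optimality property.

## Known limitations

* Influence-curve CIs without outer cross-fitting are honest here because
  the nuisance models are low-dimensional; with aggressive learners on
  small strata, enable the cross-fitting switch or expect some
  anti-conservatism.
* The disparity OR inherits XGBoost's shrinkage: on tiny training
  fractions the point estimate is pulled a few percent toward 1.
* The spline learner rests on penalized regression splines; it is a
  smooth-additive stand-in and will not capture high-order interactions
  the way boosted trees would.
* Skipped strata are a feature, not an error: with four cancer categories
  crossed with severity tertiles, small synthetic cohorts legitimately
  cannot support every cell.
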