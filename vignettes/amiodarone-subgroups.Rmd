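---
title: "Identifying subgroups with differential amiodarone response: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying subgroups with differential amiodarone response: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amioscore)
```

## The problem

Amiodarone is given to out-of-hospital cardiac arrest (OHCA) patients who
still have a shockable rhythm (VF / pulseless VT) at hospital arrival, but
randomized evidence on 30-day outcomes is equivocal, and there are
physiological reasons to expect both benefit (antiarrhythmic stabilization)
and harm (exacerbated brain injury). `amioscore` implements a
subgroup-identification pipeline for registry data of such patients: it
estimates a *linear personalized benefit score* from pre-hospital
(Utstein-style) variables and tests whether the treatment effect of
amiodarone genuinely differs between the score-defined subgroups.

Because the registry data this kind of analysis targets are not publicly
redistributable, the package ships a synthetic cohort generator with known
ground truth, plus deterministic fixtures that reproduce the published
patient-flow counts and baseline-table percentages exactly, so that every
stage of the pipeline is testable at the desk.

## The model

### Stage 1: propensity

Treatment is not randomized: amiodarone use depends on presentation (for
example, it is far more likely after three or more failed defibrillation
attempts, and far less likely in traumatic arrest). Stage 1 estimates the
propensity $e(x) = P(T = 1 \mid X = x)$ with a lasso-penalized logistic
regression (`fit_propensity()`), with the penalty chosen by k-fold
cross-validated binomial deviance. Patients are weighted by the inverse
probability of the treatment they actually received,

$$w_i = \frac{1}{T_i\,\hat e(x_i) + (1 - T_i)(1 - \hat e(x_i))} \ge 1,$$

with $\hat e$ truncated to $[\varepsilon, 1-\varepsilon]$,
$\varepsilon = 0.01$ by default, to bound the weights (`compute_weights()`).

### Stage 2: the benefit score

The score $s(x) = \beta_0 + \beta^\top x$ is fitted by minimizing the
propensity-weighted, lasso-penalized logistic likelihood loss with
*modified covariates*:

$$\sum_i w_i \log\!\left(1 + e^{-(2Y_i-1)\,(2T_i-1)\,(\beta_0 + \beta^\top x_i)}\right) + \lambda\lVert\beta\rVert_1 .$$

Multiplying the working covariates (including the score's constant column)
by $2T-1$ makes a single logistic fit target the treatment-by-covariate
interaction directly, without modeling the prognostic main effects. Under
correct weighting the pointwise population minimizer is

$$f^*(x) = \log\frac{1 + \Delta(x)}{1 - \Delta(x)}, \qquad
\Delta(x) = P(Y=1 \mid T=1, x) - P(Y=1 \mid T=0, x),$$

so $\operatorname{sign} f^*(x) = \operatorname{sign} \Delta(x)$: a patient
with $s(x) \ge 0$ is predicted to benefit from amiodarone, a patient with
$s(x) < 0$ is not (`assign_subgroup()`, cutoff 0, with the boundary on the
benefit side). Note the implied attenuation: for small effects
$f^* \approx 2\Delta \approx 2\,p(1-p)\,s_{\text{true}}$ on our generator's
logit scale, i.e. fitted coefficients are a *rescaled* version of the
data-generating interaction (about $0.24\times$ at 14% outcome prevalence).
Only the sign at 0 is decision-relevant, which is why the package reports
the score without any rescaling.

The intercept (score constant) is included and unpenalized: the decision
rule needs a free location. The penalty $\lambda$ is selected by weighted
k-fold CV at the deviance-minimizing value (`lambda_rule = "min"`; the
one-standard-error rule is available). During this selection the weights
are held fixed; they are re-estimated per training set only inside the
nested CV, where leakage matters.

### Nested cross-validation

Reporting in-sample scores would be optimistic. `cross_validated_scores()`
produces leakage-free scores: patients are partitioned into `outer_k`
folds (stratified by treatment so every training set contains both arms),
and for each fold the *entire* stage-1 + stage-2 pipeline — propensity
model, weights, benefit score, both penalties via `inner_k`-fold inner CV —
is refitted on the other folds before scoring the held-out fold. A
patient's score therefore never depends on their own treatment or outcome
(this is asserted bit-exactly in the test suite). Defaults are
`outer_k = 5`, `inner_k = 10`; these counts are design choices of this
package, exposed in `ohca_config()`.

### Inference on the interaction

With cross-validated subgroups fixed, `fit_interaction_model()` fits an
unpenalized multivariate logistic model of the 30-day outcome on the
baseline covariates used to derive the score, the in-hospital
co-interventions (ECPR, PCI, MTH), amiodarone, subgroup, and the
amiodarone-by-subgroup product; the interaction odds ratio is the estimand.
Two complementary uncertainty statements are produced:

* `bootstrap_ci()` — nonparametric bootstrap (default $B = 10{,}000$;
  percentile 2.5/97.5 interval). By default each resampled patient carries
  their subgroup label and only the interaction model is refit; a
  full-pipeline refit per replicate is available
  (`infer$bootstrap_refit_full`), since the literature is ambiguous about
  which quantity is resampled. Replicates with separation are dropped and
  counted, with a warning above 20%.
* `permutation_test()` — a one-sided test of "amiodarone is beneficial in
  the positive-score subgroup". Treatment labels are permuted without
  restriction (they are exchangeable under the no-differential-effect
  null), and **all** model-fitting stages are re-run from scratch on each
  permuted dataset; the p-value is $(1 + \#\{\text{perm} \ge
  \text{obs}\})/(1 + B)$, default $B = 999$. The sequential
  (Besag–Clifford) option `early_stop_exceed = h` stops a permutation run
  once $h$ permuted statistics reach the observed one and reports $p =
  h/m$; accept/reject decisions at any $\alpha \le h/(B+1)$ coincide with
  the fixed-$B$ test at a fraction of the cost, which is how the package's
  calibration suite affords 200 null replicates of the full pipeline.

A degenerate split (every patient on one side of the cutoff) leaves the
interaction undefined; `run_ohca_analysis()` records this and skips the
inference stage rather than failing, and a degenerate permuted replicate is
redrawn (up to `max_redraw`, after which it conservatively counts against
the alternative).

## The synthetic cohort generator

`sim_config()` / `generate_cohort()` emulate a nationwide OHCA registry
cohort of shockable-rhythm patients:

* **Covariate marginals** match the published baseline table: 78.4% male,
  68.9% witnessed, 44.9/22.6/32.5% defibrillation 0 / 1–2 / ≥3 times,
  49.4% hypothermic at arrival, 45.8% pre-hospital epinephrine, age
  truncated-normal tuned to median 67 (IQR 55–77), call-to-arrival time
  log-normal tuned to median 28 min (IQR 22–35). Durations are
  right-skewed, hence log-normal; age uses a two-parameter truncated
  normal. Covariates are drawn independently — the generator makes no
  attempt to reproduce the registry's joint dependence structure, so
  passing tests speak to the *pipeline*, not to any real-data joint
  distribution.
* **Treatment** is Bernoulli in a logistic propensity with defaults that
  reproduce the qualitative assignment pattern (more likely after repeated
  defibrillation, much less likely in traumatic arrest) and an overall
  treated fraction near the published 48.8%.
* **Outcomes**: favorable neurological status (CPC 1–2) at 30 days follows
  a logistic model whose linear predictor is prognostic main effects plus
  $(2T-1)\,s_{\text{true}}(x)/2$, which makes
  $\operatorname{sign}(s_{\text{true}})$ equal the sign of the true ITE
  exactly. Survival is favorable-neuro OR an additional survival-only
  event, so CPC 1–2 always implies being alive and the marginal rates
  (~14% and ~23%) match the published table.
* **The planted benefit structure** follows the published qualitative
  findings — benefit increases with age, call-to-arrival interval,
  hypothermia at arrival and pre-hospital epinephrine, and decreases with
  a witnessed arrest and with pre-hospital defibrillation. The magnitudes
  (score sd ≈ 1 on the log-odds scale, centered near 0) were chosen to
  match the between-subgroup treatment-effect contrast implied by the
  published subgroup outcome proportions (8% vs 5% and 16% vs 21% give a
  crude interaction OR near 2.3), so that — as in the source study — the
  heterogeneity is detectable at n ≈ 2333.
* **Co-interventions** (ECPR / PCI / MTH) are drawn downstream of
  treatment with the published arm imbalance (e.g. ECPR 55.9% vs 25.2%) to
  stress the adjusted interaction model; by default they do not feed back
  into outcomes (configurable), so they act as treatment-correlated
  adjustment noise.

`generate_cohort()` also returns the per-patient truth (propensity, benefit
score, ITE), used throughout the tests for parameter-recovery and
calibration checks.

Two deterministic fixtures complement the generator: `make_flow_fixture()`
(2958 records with exactly 14 / 227 / 308 / 76 disjoint exclusion flags)
and `make_table1_fixture()` (2333 records matching every published per-arm
categorical and outcome count, with continuous values constant at the
printed within-arm median — only counts and medians are reproduced, not
spreads). Their joint covariate structure is arbitrary (rotating block
assignment) but fixed.

## Numerical choices

* Both lasso stages are solved with `glmnet`; continuous covariates are
  standardized internally and coefficients are reported on the original
  scale. A forced penalty (including 0 for the unpenalized fit) is solved
  along a decreasing path ending at the target value with a tight
  convergence threshold, which is how the test suite compares both stages
  against an independent Newton (IRLS) oracle to $10^{-5}$.
* CV folds are assigned by stratified permutation (sizes within a stratum
  differ by at most one); every random stage derives its seed from one
  master seed through a fixed congruential map, so the whole analysis —
  including each permutation replicate's from-scratch refit — is
  bit-reproducible.
* Propensities are truncated at $\varepsilon = 0.01$ before weighting; the
  source literature is silent on truncation, and bounded weights keep the
  bootstrap stable.
* Exclusion reasons are attributed in the published order (pediatric,
  other antiarrhythmic, unlinkable, missing data), first match wins; this
  is the only attribution under which the published per-reason counts sum
  to the published total.
* Percentages are displayed with round-half-up to one decimal, the
  registry-table convention (the published text and table disagree on one
  value, 24.4 vs 24.3; the table is arithmetically consistent with
  round-half-up and is the reference).
* Hypothermia at arrival is body temperature ≤ 34 °C, and an unmeasurably
  low temperature counts as hypothermic; age and call-to-arrival time
  enter per year and per minute respectively (the published per-year OR of
  0.93 for age suggests per-year coding).

## Problem sizes used in the shipped checks

The validation suite scales the study down to desk size as its own design
choice: oracle equivalence on n ≤ 50 instances; ground-truth recovery at
n = 20,000 (observed: all planted coefficient signs recovered, ≥ 85%
subgroup agreement with the true ITE sign); permutation type-I error over
200 valid null replicates at n = 1000 with B = 99, 2 outer / 3 inner folds
and a 30-point penalty path; bootstrap coverage of a known interaction OR
over 200 replicates at n = 1000 with B = 199. The acceptance script runs
the full default pipeline at the study scale n = 2333 with B = 99
permutations and 1000 bootstrap replicates.

## Known limitations

* The score is linear and the candidate set is the fixed pre-hospital
  dictionary: no basis expansion, tree ensembles, or A-learning variants.
* Under a true null the CV-selected score is often exactly constant, so
  the subgroup split — and hence the interaction test — is undefined on
  such draws; the package reports this honestly rather than forcing a
  split.
* The bootstrap default conditions on the fixed cross-validated labels;
  score-estimation uncertainty is only propagated with
  `bootstrap_refit_full = TRUE`, at substantial cost.
* No missing-data handling (the analysis is complete-case by design), no
  time-to-event outcomes, and no multiplicity adjustment across the two
  outcomes.
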