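# amioscore

Subgroup identification for differential amiodarone response in
out-of-hospital cardiac arrest (OHCA) patients with a shockable rhythm at
hospital arrival.

Amiodarone is the standard antiarrhythmic for shock-refractory VF/pulseless
VT, yet its effect on 30-day neurological outcome is uncertain and plausibly
heterogeneous: it may stabilize some patients hemodynamically while
worsening post-arrest brain injury in others. `amioscore` is for
biostatisticians and resuscitation researchers working with Utstein-style
registry data who want to (a) estimate a per-patient benefit score from
pre-hospital variables only, and (b) test rigorously whether the treatment
effect really differs between the score-defined subgroups.

## The method

With treatment `T` (amiodarone), outcome `Y` (CPC 1–2 at 30 days, or
survival), and encoded pre-hospital covariates `x`:

1. **Propensity** — lasso-penalized logistic regression for
   `e(x) = P(T = 1 | x)`, penalty by k-fold CV; weights
   `w = 1 / (T e(x) + (1−T)(1−e(x)))` (inverse probability of the received
   treatment, propensities truncated at 0.01).
2. **Benefit score** — a linear score `s(x) = β₀ + βᵀx` minimizing the
   propensity-weighted, lasso-penalized logistic likelihood loss with
   *modified covariates*:

   `Σᵢ wᵢ log(1 + exp(−(2Yᵢ−1)(2Tᵢ−1)(β₀ + βᵀxᵢ))) + λ‖β‖₁`

   The sign of the population minimizer equals the sign of the individual
   treatment effect, so `s(x) ≥ 0` predicts benefit and `s(x) < 0` predicts
   no benefit.
3. **Nested cross-validation** — held-out scores from outer folds, with
   both penalties re-optimized by inner CV and the propensity re-estimated
   per training set; no patient's label depends on their own data.
4. **Inference** — unpenalized multivariate logistic model of `Y` on the
   baseline covariates, co-interventions (ECPR/PCI/MTH), treatment,
   subgroup, and the treatment×subgroup product; percentile bootstrap CI
   for the interaction OR and a one-sided permutation test in which *every*
   fitting stage is re-run from scratch under permuted treatment.

A synthetic registry-like cohort generator with known ground truth
(`sim_config()` / `generate_cohort()`) and deterministic fixtures matching
the published patient-flow and baseline-table arithmetic
(`make_flow_fixture()` / `make_table1_fixture()`) make the whole pipeline
testable without access to the restricted registry. See the vignette
(`vignettes/amiodarone-subgroups.Rmd`) for the full model account.

## Worked example

```r
library(amioscore)

cfg    <- sim_config(n_patients = 2333, seed = 7)   # registry-scale cohort
cohort <- generate_cohort(cfg)
config <- ohca_config(seed = 42, infer = list(bootstrap_B = 500L, perm_B = 99L))
ana    <- run_ohca_analysis(cohort$records, config, outcomes = "neuro")
ana
#> OHCA amiodarone subgroup analysis
#>   records: 2333  retained: 2333  excluded: 0
#>   [neuro] benefit subgroup: 42.3%; interaction OR 3.091 (95% CI 1.876-5.474), one-sided p = 0.01

ana$outcomes$neuro$developed$model
#> Personalized benefit score (modified-covariate weighted lasso)
#> outcome: neuro  lambda = 0.001285
#> s(x) = -0.6038 + 0.006657*age - 0.06253*sex_male + 0.003709*call_to_arrival_min
#>        + 0.08977*cause_trauma - 0.1096*witness - 0.1606*defib_1or2
#>        - 0.2766*defib_3plus + 0.2311*hypothermia + 0.2943*prehosp_epi
```

Reading this output: 42.3% of the simulated patients have a cross-validated
score ≥ 0 (predicted to benefit). In that subgroup the amiodarone odds
ratio for a favorable neurological outcome is 3.09 times the odds ratio in
the no-benefit subgroup, the bootstrap 95% CI (1.88–5.47) excludes 1, and
the from-scratch permutation test gives one-sided p = 0.01 — the pipeline
detects the heterogeneity that the generator planted (benefit increasing
with age, call-to-arrival interval, hypothermia and pre-hospital
epinephrine; decreasing with a witnessed arrest and pre-hospital
defibrillation — visible in the recovered coefficient signs above). The
fixed-fixture stages reproduce the published arithmetic exactly, e.g.

```r
apply_exclusions(make_flow_fixture())$tally
#>            pediatric other_antiarrhythmic           unlinkable
#>                   14                  227                  308
#>         missing_data             retained                total
#>                   76                 2333                 2958
```

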