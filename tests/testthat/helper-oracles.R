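# Independent oracles and small cohort builders used across the suite.

# Weighted logistic MLE by damped Newton (IRLS) on the design Z (which must
# already contain any constant column). Independent of the glmnet-based
# fitting path: direct second-order optimization of
#   sum_i w_i * log(1 + exp(-(2 y_i - 1) * z_i' b))
irls_logistic <- function(Z, y, w = rep(1, length(y)), tol = 1e-12,
                          maxit = 200) {
  b <- rep(0, ncol(Z))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(Z %*% b)
    p <- plogis(eta)
    grad <- crossprod(Z, w * (y - p))
    H <- crossprod(Z, Z * (w * p * (1 - p)))
    step <- solve(H, grad)
    b_new <- b + step
    if (max(abs(b_new - b)) < tol) return(as.numeric(b_new))
    b <- b_new
  }
  as.numeric(b)
}

# negative weighted log-likelihood, for sanity-checking oracle minima
wlogistic_loss <- function(b, Z, y, w) {
  eta <- as.numeric(Z %*% b)
  sum(w * log1p(exp(-(2 * y - 1) * eta)))
}

# simulated analysis cohort (records run through the exclusion/encoding stage)
make_sim_cohort <- function(n, seed = 1, ...) {
  g <- generate_cohort(sim_config(n_patients = n, seed = seed, ...))
  list(cohort = apply_exclusions(g$records)$cohort, truth = g$truth,
       records = g$records)
}

null_benefit <- rep(0, 11)
randomized_propensity <- rep(0, 11)  # e(x) = 0.5 for everyone

# tiny hand-built raw cohort with every dictionary column present
toy_records <- function(n, amiodarone = rep(0L, n), cpc30 = rep(0L, n),
                        survival30 = cpc30, defib = rep("0", n),
                        age = rep(60, n), sex = rep(1L, n)) {
  data.frame(patient_id = sprintf("T%04d", seq_len(n)), age = age, sex = sex,
             call_to_arrival_min = rep(25, n), cause_trauma = rep(0L, n),
             witness = rep_len(c(1L, 0L), n), bystander = rep_len(c(0L, 1L), n),
             defib_category = defib, hypothermia_arrival = rep_len(c(0L, 1L), n),
             prehosp_epi = rep(0L, n), amiodarone = amiodarone,
             ecpr = rep(0L, n), pci = rep(0L, n), mth = rep(0L, n),
             cpc30 = cpc30, survival30 = survival30,
             stringsAsFactors = FALSE)
}
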