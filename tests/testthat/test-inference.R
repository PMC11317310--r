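# Builds a cohort whose outcome depends only on the treatment-by-subgroup
# cell, with exact cell counts, so the saturated interaction log-OR has a
# closed form on the cell proportions.
saturated_toy <- function(n_cell = 400,
                          p = c(p00 = 0.20, p01 = 0.30, p10 = 0.25, p11 = 0.60)) {
  cells <- expand.grid(trt = 0:1, sub = 0:1)
  recs <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    tr <- cells$trt[k]; sb <- cells$sub[k]
    pk <- p[paste0("p", tr, sb)]
    y <- rep(c(1L, 0L), c(round(pk * n_cell), n_cell - round(pk * n_cell)))
    r <- toy_records(n_cell, amiodarone = rep(as.integer(tr), n_cell),
                     cpc30 = y)
    r$patient_id <- sprintf("C%d%d_%04d", tr, sb, seq_len(n_cell))
    r$sub <- sb
    r
  }))
  co <- apply_exclusions(recs[, setdiff(names(recs), "sub")])$cohort
  list(cohort = co,
       subgroup = factor(ifelse(recs$sub == 1, "benefit", "no_benefit"),
                         levels = c("no_benefit", "benefit")))
}

test_that("the saturated interaction log-OR equals the closed-form cross-ratio", {
  p <- c(p00 = 0.20, p01 = 0.30, p10 = 0.25, p11 = 0.60)
  toy <- saturated_toy(400, p)
  fit <- fit_interaction_model(toy$cohort, toy$subgroup, "neuro",
                               covariates = character(0))
  lodds <- function(q) log(q / (1 - q))
  closed <- (lodds(p["p11"]) - lodds(p["p01"])) - (lodds(p["p10"]) - lodds(p["p00"]))
  expect_equal(fit$interaction_log_or, unname(closed), tolerance = 1e-8)
  # replicating every row leaves the MLE unchanged
  dup <- amioscore:::subset_cohort(toy$cohort, rep(seq_len(1600), 2))
  fit2 <- fit_interaction_model(dup, rep(toy$subgroup, 2), "neuro",
                                covariates = character(0))
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-8)
})

test_that("with a coin-flip outcome all adjusted ORs are near one", {
  d <- make_sim_cohort(10000, seed = 31,
                       prognostic_coefs = rep(0, 11),
                       benefit_coefs = null_benefit)
  set.seed(32)
  sub <- factor(ifelse(runif(10000) < 0.5, "benefit", "no_benefit"),
                levels = c("no_benefit", "benefit"))
  fit <- fit_interaction_model(d$cohort, sub, "neuro")
  ors <- fit$table$or
  names(ors) <- fit$table$term
  # per-year / per-minute terms are on much finer scales; compare binaries
  binaries <- setdiff(fit$table$term, c("age", "call_to_arrival_min"))
  expect_true(all(ors[binaries] > 0.9 & ors[binaries] < 1.1))
  expect_true(all(ors[c("age", "call_to_arrival_min")] > 0.99 &
                  ors[c("age", "call_to_arrival_min")] < 1.01))
})

test_that("interaction model rejects degenerate inputs and flags separation", {
  toy <- saturated_toy(50)
  expect_error(fit_interaction_model(toy$cohort,
                                     rep("benefit", 200), "neuro"),
               "both subgroups", ignore.case = TRUE)
  # outcome perfectly determined by treatment in one cell -> separation flag
  sep <- saturated_toy(60, p = c(p00 = 0.5, p01 = 0.5, p10 = 0.5, p11 = 1))
  fit <- fit_interaction_model(sep$cohort, sep$subgroup, "neuro",
                               covariates = character(0))
  expect_true(fit$separation)
})

test_that("bootstrap intervals are deterministic in the seed and validate B", {
  toy <- saturated_toy(150)
  a <- bootstrap_ci(toy$cohort, toy$subgroup, "neuro", B = 120, seed = 5)
  b <- bootstrap_ci(toy$cohort, toy$subgroup, "neuro", B = 120, seed = 5)
  expect_identical(a$ci, b$ci)
  expect_lt(a$ci[1], a$point)
  expect_gt(a$ci[2], a$point)
  c2 <- bootstrap_ci(toy$cohort, toy$subgroup, "neuro", B = 120, seed = 6)
  expect_false(identical(a$ci, c2$ci))
  expect_error(bootstrap_ci(toy$cohort, toy$subgroup, "neuro", B = 50), "B must")
})

test_that("percentile bootstrap and Wald intervals overlap substantially at large n", {
  toy <- saturated_toy(1000)
  fit <- fit_interaction_model(toy$cohort, toy$subgroup, "neuro",
                               covariates = character(0))
  z <- qnorm(0.975)
  wald <- exp(fit$interaction_log_or + c(-z, z) * fit$interaction_se)
  boot <- bootstrap_ci(toy$cohort, toy$subgroup, "neuro", B = 199, seed = 7)
  lo <- max(wald[1], boot$ci[1]); hi <- min(wald[2], boot$ci[2])
  jaccard <- (hi - lo) / (max(wald[2], boot$ci[2]) - min(wald[1], boot$ci[1]))
  expect_gte(jaccard, 0.5)
})

test_that("the permutation p-value follows the add-one formula", {
  pp <- amioscore:::perm_pvalue
  expect_equal(pp(2, rep(1, 19)), 1 / 20)      # observed beats all 19
  expect_equal(pp(1, rep(1, 19)), 1)           # all permutations tie
  expect_equal(pp(0.5, c(rep(0, 90), rep(1, 9))), 10 / 100)
})

test_that("a from-scratch permutation test runs, is deterministic, and early stopping matches", {
  d <- make_sim_cohort(700, seed = 41)
  cfg <- ohca_config(seed = 42, cv = list(outer_k = 2L, inner_k = 3L),
                     propensity = list(nlambda = 30L, lambda_min_ratio = 0.01),
                     benefit = list(nlambda = 30L, lambda_min_ratio = 0.01))
  pt <- permutation_test(d$cohort, cfg, "neuro", B = 19, seed = 43)
  expect_length(pt$stats, 19)
  expect_true(pt$p > 0 && pt$p <= 1)
  pt2 <- permutation_test(d$cohort, cfg, "neuro", B = 19, seed = 43)
  expect_identical(pt$p, pt2$p)
  es <- permutation_test(d$cohort, cfg, "neuro", B = 19, seed = 43,
                         early_stop_exceed = 1L)
  # identical permutation stream: decisions at alpha <= 1/20 coincide
  expect_identical(es$p <= 0.05, pt$p <= 0.05)
  expect_error(permutation_test(d$cohort, cfg, "neuro", B = 10), "B must")
})

test_that("subgroup outcome tables conserve counts and reproduce planted proportions", {
  # planted proportions mirroring the published subgroup outcome pattern
  toy <- saturated_toy(200, p = c(p00 = 0.09, p01 = 0.15, p10 = 0.30, p11 = 0.28))
  tab <- subgroup_outcome_table(toy$cohort, toy$subgroup)
  expect_equal(sum(tab$neuro$n), 800)
  expect_equal(tab$neuro$proportion["amio_pos", "benefit"], 0.28,
               tolerance = 1e-9)
  expect_equal(tab$neuro$proportion["amio_neg", "no_benefit"], 0.09,
               tolerance = 1e-9)
  expect_true(all(tab$survival$proportion >= 0 & tab$survival$proportion <= 1))
  # degenerate: everyone treated and benefit-labelled -> one populated cell
  r <- toy_records(30, amiodarone = rep(1L, 30), cpc30 = rep_len(c(1L, 0L), 30))
  co <- apply_exclusions(r)$cohort
  one <- subgroup_outcome_table(co, factor(rep("benefit", 30),
                                           levels = c("no_benefit", "benefit")))
  expect_equal(unname(one$neuro$n["amio_pos", "benefit"]), 30)
  expect_equal(unname(one$neuro$proportion["amio_pos", "benefit"]), 0.5)
})
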