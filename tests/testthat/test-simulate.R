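test_that("identical config and seed reproduce the cohort and truth exactly", {
  cfg <- sim_config(n_patients = 500, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(sim_config(n_patients = 500, seed = 43))
  expect_false(identical(a$records$amiodarone, c2$records$amiodarone))
})

test_that("null benefit coefficients give exactly zero ITE for every patient", {
  g <- generate_cohort(sim_config(n_patients = 300, benefit_coefs = null_benefit,
                                  seed = 7))
  expect_true(all(g$truth$true_benefit_score == 0))
  expect_true(all(g$truth$true_ite == 0))
})

test_that("zero propensity coefficients randomize treatment at one half", {
  g <- generate_cohort(sim_config(n_patients = 20000,
                                  propensity_coefs = randomized_propensity,
                                  seed = 11))
  expect_true(all(g$truth$true_propensity == 0.5))
  expect_lt(abs(mean(g$records$amiodarone) - 0.5), 0.01)
})

test_that("empirical marginals match the configured values at large n", {
  m <- amioscore:::default_marginals()
  g <- generate_cohort(sim_config(n_patients = 50000, seed = 5))
  r <- g$records
  expect_lt(abs(mean(r$witness) - 0.689), 0.01)
  emp <- c(sex = mean(r$sex), cause_trauma = mean(r$cause_trauma),
           bystander = mean(r$bystander),
           hypothermia = mean(r$hypothermia_arrival),
           prehosp_epi = mean(r$prehosp_epi),
           defib0 = mean(r$defib_category == "0"),
           defib12 = mean(r$defib_category == "1_2"),
           defib3 = mean(r$defib_category == "3plus"))
  target <- c(m$sex_male, m$cause_trauma, m$bystander, m$hypothermia,
              m$prehosp_epi, m$defib)
  expect_true(all(abs(emp - target) < 0.01))
  # continuous targets: medians near the configured registry values
  expect_lt(abs(median(r$age) - 67), 1.5)
  expect_lt(abs(median(r$call_to_arrival_min) - 28), 1.5)
})

test_that("stored ITE equals the outcome-model arm difference recomputed independently", {
  cfg <- sim_config(n_patients = 400, seed = 9)
  g <- generate_cohort(cfg)
  X <- encode_covariates(g$records)$X
  # naive per-patient loop, independent of the generator's vectorized path
  for (i in seq_len(50)) {
    s <- unname(cfg$benefit_coefs[1] + sum(cfg$benefit_coefs[-1] * X[i, ]))
    prog <- unname(cfg$prognostic_coefs[1] + sum(cfg$prognostic_coefs[-1] * X[i, ]))
    ite <- plogis(prog + s / 2) - plogis(prog - s / 2)
    expect_equal(g$truth$true_ite[i], ite, tolerance = 1e-12)
    expect_equal(g$truth$true_benefit_score[i], s, tolerance = 1e-12)
    expect_identical(sign(g$truth$true_ite[i]), sign(g$truth$true_benefit_score[i]))
  }
})

test_that("under a fully null randomized design the outcome is independent of treatment", {
  for (i in 1:5) {
    g <- generate_cohort(sim_config(n_patients = 10000,
                                    benefit_coefs = null_benefit,
                                    propensity_coefs = randomized_propensity,
                                    seed = 100 + i))
    p <- suppressWarnings(
      stats::chisq.test(table(g$records$amiodarone, g$records$cpc30)))$p.value
    expect_gt(p, 0.001)
  }
})

test_that("survival at 30 days always includes favorable neurological outcome", {
  g <- generate_cohort(sim_config(n_patients = 2000, seed = 13))
  expect_true(all(g$records$survival30 >= g$records$cpc30))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(covariate_marginals = utils::modifyList(
    amioscore:::default_marginals(), list(witness = 1.2))), "probabilities")
  expect_error(sim_config(covariate_marginals = utils::modifyList(
    amioscore:::default_marginals(), list(defib = c(`0` = .5, `1_2` = .2, `3plus` = .2)))),
    "sum to 1")
  expect_error(sim_config(benefit_coefs = c(0, 1)), "length")
})

test_that("co-interventions are imbalanced by arm as configured", {
  g <- generate_cohort(sim_config(n_patients = 20000, seed = 21))
  r <- g$records
  expect_lt(abs(mean(r$ecpr[r$amiodarone == 1]) - 0.559), 0.02)
  expect_lt(abs(mean(r$ecpr[r$amiodarone == 0]) - 0.252), 0.02)
  expect_gt(mean(r$pci[r$amiodarone == 1]), mean(r$pci[r$amiodarone == 0]))
  expect_gt(mean(r$mth[r$amiodarone == 1]), mean(r$mth[r$amiodarone == 0]))
})
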