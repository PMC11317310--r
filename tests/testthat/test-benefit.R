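test_that("the modified design multiplies each row (and the constant) by 2T-1", {
  set.seed(1)
  X <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("x", 1:4)))
  trt <- c(1L, 0L, 1L, 0L, 0L)
  md <- build_modified_design(X, trt)
  expect_equal(md$Z[1, -1], X[1, ])            # treated row unchanged
  expect_equal(md$Z[2, -1], -X[2, ])           # control row negated
  expect_equal(unname(md$Z[, 1]), 2 * trt - 1) # working constant column
  # permuting T flips exactly the rows whose label changed (naive loop check)
  perm <- c(2L, 1L, 3L, 5L, 4L)
  md2 <- build_modified_design(X, trt[perm])
  for (i in 1:5) {
    expected <- c(2 * trt[perm][i] - 1, X[i, ] * (2 * trt[perm][i] - 1))
    expect_equal(unname(md2$Z[i, ]), unname(expected))
  }
  expect_error(build_modified_design(X, c(1, 2, 0, 0, 1)), "0/1")
})

test_that("a saturated penalty leaves only the unpenalized score constant", {
  d <- make_sim_cohort(300, seed = 2)
  md <- build_modified_design(d$cohort$X, d$cohort$T)
  fit <- fit_benefit_model(md, d$cohort$Y_neuro, rep(1, 300), lambda = 20)
  expect_true(all(fit$beta == 0))
  s <- score_patients(fit, d$cohort$X)
  expect_equal(s, rep(fit$beta0, 300))
})

test_that("the unpenalized weighted fit matches an independent Newton MLE", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    n <- 40
    X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
    trt <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, plogis(0.2 + (2 * trt - 1) * (0.4 + 0.9 * X[, 1]) / 2))
    w <- 1 + runif(n)  # genuinely non-uniform weights
    md <- build_modified_design(X, trt)
    fit <- fit_benefit_model(md, y, w, lambda = 0)
    oracle <- irls_logistic(md$Z, y, w)
    est <- c(fit$beta0, fit$beta)
    expect_lt(max(abs(est - oracle)), 1e-5)
    # oracle really is at a lower-or-equal loss than any nearby perturbation
    base <- wlogistic_loss(oracle, md$Z, y, w)
    expect_lt(base, wlogistic_loss(oracle + 0.01, md$Z, y, w))
  }
})

test_that("scores are the linear predictor, matching a naive dot product", {
  d <- make_sim_cohort(60, seed = 3)
  md <- build_modified_design(d$cohort$X, d$cohort$T)
  fit <- fit_benefit_model(md, d$cohort$Y_neuro, rep(1, 60), lambda = 0.05)
  s <- score_patients(fit, d$cohort$X)
  naive <- vapply(seq_len(60), function(i)
    fit$beta0 + sum(fit$beta * d$cohort$X[i, names(fit$beta)]), 0)
  expect_equal(s, naive, tolerance = 1e-12)
  expect_equal(predict(fit, d$cohort$X), s)
  expect_error(score_patients(fit, matrix(0, 2, 2)), "columns")
})

test_that("subgroup assignment uses score >= 0 with the boundary on the benefit side", {
  lab <- assign_subgroup(c(0, -1e-9, 0.3, -2))
  expect_equal(as.character(lab), c("benefit", "no_benefit", "benefit", "no_benefit"))
  one_sided <- assign_subgroup(c(0.2, 0.4))
  expect_true(isTRUE(attr(one_sided, "degenerate")))
  expect_error(assign_subgroup(c(1, NaN)), "finite")
  expect_error(assign_subgroup(c(1, Inf)), "finite")
})

test_that("flipping all treatment labels negates the fitted score", {
  d <- make_sim_cohort(800, seed = 5)
  co <- d$cohort
  pfit <- fit_propensity(co$X, co$T, seed = 6)
  w <- compute_weights(pfit, co$T)
  fit <- fit_benefit_model(build_modified_design(co$X, co$T), co$Y_neuro, w,
                           lambda = 0.02)
  # flip arms; the propensity model refit on 1-T gives mirrored e, same weights
  pfit2 <- fit_propensity(co$X, 1L - co$T, seed = 6)
  w2 <- compute_weights(pfit2, 1L - co$T)
  fit2 <- fit_benefit_model(build_modified_design(co$X, 1L - co$T), co$Y_neuro,
                            w2, lambda = 0.02)
  expect_equal(w2, w, tolerance = 1e-6)
  expect_equal(c(fit2$beta0, fit2$beta), -c(fit$beta0, fit$beta),
               tolerance = 1e-4)
})

test_that("degenerate outcomes are rejected", {
  d <- make_sim_cohort(50, seed = 7)
  md <- build_modified_design(d$cohort$X, d$cohort$T)
  expect_error(fit_benefit_model(md, rep(1L, 50), rep(1, 50)), "egenerate")
})

test_that("with no planted heterogeneity the CV-selected score is usually constant", {
  allzero <- 0
  for (i in 1:10) {
    d <- make_sim_cohort(10000, seed = 200 + i, benefit_coefs = null_benefit)
    dev <- in_sample_scores(d$cohort, ohca_config(seed = 300 + i))
    if (all(dev$model$beta == 0)) allzero <- allzero + 1
  }
  expect_gte(allzero, 8)
})
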