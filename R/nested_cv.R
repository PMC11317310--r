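# Nested cross-validation: outer folds yield held-out (leakage-free) scores;
# the lasso penalties of both fitting stages are re-optimized by inner CV
# within each outer training set, and the propensity model (hence the
# weights) is itself re-estimated per outer training set.

#' Build a reproducible stratified cross-validation plan
#'
#' @param n number of patients.
#' @param outer_k outer folds (held-out scoring), `2 <= outer_k <= n`.
#' @param inner_k inner folds (penalty selection inside each training set).
#' @param seed integer seed.
#' @param stratify_by optional vector (typically the treatment indicator);
#'   fold sizes within each stratum differ by at most one.
#' @return object of class `cv_plan` with the per-patient outer fold label.
#' @export
make_cv_plan <- function(n, outer_k = 5L, inner_k = 10L, seed = 1L,
                         stratify_by = NULL) {
  if (outer_k > n) stop_config("outer_k exceeds the number of patients")
  if (outer_k < 2 || inner_k < 2) stop_config("fold counts must be >= 2")
  strata <- if (is.null(stratify_by)) rep(1L, n) else stratify_by
  if (length(strata) != n) stop_config("stratify_by must have length n")
  fold <- make_foldid(strata, outer_k, seed)
  structure(list(n = n, outer_k = as.integer(outer_k),
                 inner_k = as.integer(inner_k), seed = as.integer(seed),
                 fold = fold, stratified = !is.null(stratify_by)),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("Nested CV plan: n =", x$n, " outer folds =", x$outer_k,
      " inner folds =", x$inner_k,
      if (x$stratified) "(stratified)" else "", "\n")
  print(table(fold = x$fold))
  invisible(x)
}

#' Cross-validated benefit scores and subgroup labels
#'
#' For each outer fold, the propensity model, the weights, and the benefit
#' score are fitted on the patients *outside* the fold (penalties selected by
#' inner CV); the held-out patients are then scored with that model. Each
#' patient's score therefore never depends on their own treatment or outcome.
#' Subgroups are assigned at the score-zero cutoff.
#'
#' @param cohort an `ohca_cohort`.
#' @param plan a [make_cv_plan()]; defaults to a treatment-stratified plan
#'   from the config.
#' @param config an [ohca_config()].
#' @param outcome `"neuro"` or `"survival"`: which outcome the score targets.
#' @return data.frame (`patient_id`, `cv_score`, `subgroup`) of class
#'   `score_assignment` with attributes `provenance = "cross_validated"` and
#'   `fold_models` (per-fold selected penalties).
#' @export
cross_validated_scores <- function(cohort, plan = NULL, config = ohca_config(),
                                   outcome = NULL) {
  outcome <- outcome %||% config$benefit$outcome
  n <- n_patients(cohort)
  if (is.null(plan))
    plan <- make_cv_plan(n, config$cv$outer_k, config$cv$inner_k,
                         seed = derive_seed(config$seed, "cv_plan"),
                         stratify_by = cohort$T)
  y <- cohort_outcome(cohort, outcome)
  scores <- numeric(n)
  fold_models <- vector("list", plan$outer_k)
  for (f in seq_len(plan$outer_k)) {
    test <- plan$fold == f
    tr <- which(!test)
    if (length(unique(cohort$T[tr])) < 2)
      stop_config("training set for outer fold ", f,
                  " contains a single treatment arm")
    pfit <- fit_propensity(cohort$X[tr, , drop = FALSE], cohort$T[tr],
                           cv_folds = plan$inner_k,
                           seed = derive_seed(config$seed, paste0("prop_f", f)),
                           lambda_rule = config$propensity$lambda_rule,
                           truncation = config$propensity$truncation,
                           nlambda = config$propensity$nlambda,
                           lambda_min_ratio = config$propensity$lambda_min_ratio)
    w <- compute_weights(pfit, cohort$T[tr])
    md <- build_modified_design(cohort$X[tr, , drop = FALSE], cohort$T[tr])
    bfit <- fit_benefit_model(md, y[tr], w, cv_folds = plan$inner_k,
                              seed = derive_seed(config$seed, paste0("ben_f", f)),
                              lambda_rule = config$benefit$lambda_rule,
                              outcome = outcome,
                              nlambda = config$benefit$nlambda,
                              lambda_min_ratio = config$benefit$lambda_min_ratio)
    scores[test] <- score_patients(bfit, cohort$X[test, , drop = FALSE])
    fold_models[[f]] <- list(lambda_prop = pfit$lambda, lambda_ben = bfit$lambda)
  }
  out <- data.frame(patient_id = cohort$patient_id, cv_score = scores,
                    subgroup = assign_subgroup(scores),
                    stringsAsFactors = FALSE)
  class(out) <- c("score_assignment", "data.frame")
  attr(out, "provenance") <- "cross_validated"
  attr(out, "outcome") <- outcome
  attr(out, "fold_models") <- fold_models
  out
}

#' In-sample benefit scores (the "developed" score)
#'
#' Fits both stages once on the full cohort and scores every patient with the
#' resulting model. Used for reporting the scoring equation itself; subgroup
#' inference uses the cross-validated scores.
#'
#' @inheritParams cross_validated_scores
#' @return list with `propensity` (`propensity_fit`), `model`
#'   (`benefit_model`) and `assignment` (a `score_assignment` with
#'   provenance `"in_sample"`).
#' @export
in_sample_scores <- function(cohort, config = ohca_config(), outcome = NULL) {
  outcome <- outcome %||% config$benefit$outcome
  y <- cohort_outcome(cohort, outcome)
  pfit <- fit_propensity(cohort$X, cohort$T,
                         cv_folds = config$propensity$cv_folds,
                         seed = derive_seed(config$seed, "prop_full"),
                         lambda_rule = config$propensity$lambda_rule,
                         truncation = config$propensity$truncation,
                         nlambda = config$propensity$nlambda,
                         lambda_min_ratio = config$propensity$lambda_min_ratio)
  w <- compute_weights(pfit, cohort$T)
  md <- build_modified_design(cohort$X, cohort$T)
  bfit <- fit_benefit_model(md, y, w, cv_folds = config$benefit$cv_folds,
                            seed = derive_seed(config$seed, "ben_full"),
                            lambda_rule = config$benefit$lambda_rule,
                            outcome = outcome,
                            nlambda = config$benefit$nlambda,
                            lambda_min_ratio = config$benefit$lambda_min_ratio)
  sc <- score_patients(bfit, cohort$X)
  out <- data.frame(patient_id = cohort$patient_id, cv_score = sc,
                    subgroup = assign_subgroup(sc), stringsAsFactors = FALSE)
  class(out) <- c("score_assignment", "data.frame")
  attr(out, "provenance") <- "in_sample"
  attr(out, "outcome") <- outcome
  list(propensity = pfit, model = bfit, assignment = out)
}
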