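# Stage 2: the personalized benefit score. A linear score s(x) = b0 + b'x is
# fitted by minimizing the propensity-weighted, lasso-penalized logistic
# likelihood loss with modified covariates:
#
#   sum_i w_i * log(1 + exp(-(2*Y_i - 1) * (2*T_i - 1) * (b0 + b'x_i)))
#     + lambda * ||b||_1
#
# Multiplying the working covariates (and the score's constant column) by
# (2T - 1) makes a single logistic fit target the treatment-by-covariate
# interaction directly, without modeling prognostic main effects. Under
# inverse-probability weighting the population minimizer has
# sign(s(x)) = sign(ITE(x)), which is what the score-at-zero decision rule
# uses.

#' Build the modified-covariate working design
#'
#' Each row's working covariates are the original covariates, plus the
#' score's constant column, multiplied by `2T - 1`: rows of treated patients
#' are unchanged, rows of untreated patients are negated. A logistic fit on
#' this design with the outcome as response then has linear predictor
#' `(2T - 1) * (b0 + b'x)`.
#'
#' @param X encoded covariate matrix.
#' @param treatment 0/1 treatment indicator.
#' @return list with `Z` (working design: column `score_const` then the
#'   sign-flipped covariates) and `treatment`.
#' @export
build_modified_design <- function(X, treatment) {
  treatment <- as.integer(treatment)
  if (!all(treatment %in% c(0L, 1L)))
    stop_config("treatment must be 0/1")
  s <- 2 * treatment - 1
  Z <- cbind(score_const = s, X * s)
  list(Z = Z, treatment = treatment)
}

#' Fit the linear personalized benefit score
#'
#' Minimizes the propensity-weighted, lasso-penalized modified-covariate
#' logistic loss (see [build_modified_design()]). The score constant is
#' unpenalized; covariates are standardized internally by the solver and
#' coefficients are returned on the original scale. The penalty is selected
#' by weighted k-fold cross-validated deviance with the weights held fixed
#' (they are re-estimated per training set only inside the nested CV, where
#' leakage matters).
#'
#' @param modified a list from [build_modified_design()].
#' @param y 0/1 outcome vector.
#' @param weights propensity weights from [compute_weights()].
#' @param cv_folds folds for the penalty search (stratified by treatment).
#' @param seed integer seed for fold assignment.
#' @param lambda_rule `"min"` or `"1se"`.
#' @param lambda optional forced penalty (skips CV).
#' @param outcome label recording which outcome the score targets.
#' @param nlambda,lambda_min_ratio resolution and depth of the candidate
#'   penalty path (solver defaults when `NULL`).
#' @return object of class `benefit_model` with `beta0`, `beta` (named, on
#'   the original covariate scale), selected `lambda`, and settings.
#' @export
fit_benefit_model <- function(modified, y, weights, cv_folds = 10L, seed = 1L,
                              lambda_rule = c("min", "1se"), lambda = NULL,
                              outcome = "neuro", nlambda = 100L,
                              lambda_min_ratio = NULL) {
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop_config("degenerate outcome: all responses identical")
  Z <- modified$Z
  pf <- c(0, rep(1, ncol(Z) - 1))
  res <- glmnet_logistic(Z, y, weights = weights, cv_folds = cv_folds,
                         seed = seed, lambda_rule = match.arg(lambda_rule),
                         lambda = lambda,
                         foldid = if (is.null(lambda))
                           make_foldid(modified$treatment, cv_folds, seed)
                         else NULL,
                         intercept = FALSE, penalty.factor = pf,
                         nlambda = nlambda, lambda_min_ratio = lambda_min_ratio)
  co <- res$coefficients
  # glmnet's own (suppressed) intercept is identically 0; the score constant
  # lives in the unpenalized score_const column
  beta0 <- unname(co["score_const"])
  beta <- co[setdiff(names(co), c("(Intercept)", "score_const"))]
  structure(list(beta0 = beta0, beta = beta, lambda = res$lambda,
                 outcome_used = outcome, cv_folds = cv_folds, seed = seed,
                 lambda_rule = match.arg(lambda_rule)),
            class = "benefit_model")
}

#' @export
print.benefit_model <- function(x, digits = 4, ...) {
  cat("Personalized benefit score (modified-covariate weighted lasso)\n")
  cat("outcome:", x$outcome_used, " lambda =", signif(x$lambda, digits), "\n")
  cat("s(x) = ", signif(x$beta0, digits), sep = "")
  nz <- x$beta[x$beta != 0]
  if (length(nz))
    cat(paste0(ifelse(nz > 0, " + ", " - "), signif(abs(nz), digits), "*",
               names(nz), collapse = ""))
  cat("\n")
  invisible(x)
}

#' @export
coef.benefit_model <- function(object, ...) {
  c("(score_const)" = object$beta0, object$beta)
}

#' Score patients with a fitted benefit model
#'
#' @param model a `benefit_model`.
#' @param X encoded covariate matrix with the model's covariate columns.
#' @return numeric scores `s_i = b0 + b'x_i`.
#' @export
score_patients <- function(model, X) {
  if (is.null(colnames(X)) || !all(names(model$beta) %in% colnames(X)))
    stop_config("covariate columns of X do not match the model")
  X <- X[, names(model$beta), drop = FALSE]
  as.numeric(model$beta0 + X %*% model$beta)
}

#' @export
predict.benefit_model <- function(object, newdata, ...) {
  score_patients(object, newdata)
}

#' Assign benefit subgroups from scores
#'
#' A score at or above the cutoff predicts a beneficial effect of amiodarone;
#' below it, no benefit is expected.
#'
#' @param scores numeric score vector (must be finite).
#' @param cutoff decision threshold, 0 by default.
#' @return factor with levels `no_benefit`, `benefit`; if every patient lands
#'   in one subgroup the result carries attribute `degenerate = TRUE`.
#' @export
assign_subgroup <- function(scores, cutoff = 0) {
  if (any(!is.finite(scores)))
    stop_config("scores must be finite")
  lab <- factor(ifelse(scores >= cutoff, "benefit", "no_benefit"),
                levels = c("no_benefit", "benefit"))
  if (length(unique(lab)) < 2 && length(lab) > 0)
    attr(lab, "degenerate") <- TRUE
  lab
}
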