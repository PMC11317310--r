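# Stage 1: treatment-assignment (propensity) model. Lasso-penalized logistic
# regression of amiodarone on the pre-hospital covariates, penalty chosen by
# k-fold cross-validation; inverse-probability-of-received-treatment weights.

# fold labels stratified so every fold keeps the stratum proportions;
# sizes within a stratum differ by at most one
make_foldid <- function(strata, k, seed) {
  foldid <- integer(length(strata))
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  foldid
}

# Fit a lasso-penalized logistic model; either CV-select lambda or use a
# forced lambda embedded in a decreasing path (glmnet converges far more
# reliably along a path than cold at a single penalty).
glmnet_logistic <- function(x, y, weights = NULL, cv_folds = 10L, seed = 1L,
                            lambda_rule = c("min", "1se"), lambda = NULL,
                            foldid = NULL, intercept = TRUE,
                            penalty.factor = rep(1, ncol(x)),
                            nlambda = 100L, lambda_min_ratio = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  if (is.null(weights)) weights <- rep(1, length(y))
  args <- list(family = "binomial", weights = weights, intercept = intercept,
               penalty.factor = penalty.factor, nlambda = nlambda)
  if (!is.null(lambda_min_ratio)) args$lambda.min.ratio <- lambda_min_ratio
  if (!is.null(lambda)) {
    base <- do.call(glmnet::glmnet, c(list(x = x, y = y), args))
    lams <- base$lambda[base$lambda > lambda]
    path <- c(lams, lambda)
    fit <- glmnet::glmnet(x, y, family = "binomial", weights = weights,
                          intercept = intercept,
                          penalty.factor = penalty.factor,
                          lambda = path, thresh = 1e-14, maxit = 10^6)
    beta <- as.numeric(stats::coef(fit, s = lambda))
    return(list(coefficients = setNames(beta, c("(Intercept)", colnames(x))),
                lambda = lambda, cv = NULL))
  }
  if (is.null(foldid)) foldid <- make_foldid(y, cv_folds, seed)
  cv <- do.call(glmnet::cv.glmnet,
                c(list(x = x, y = y, foldid = foldid,
                       type.measure = "deviance"), args))
  lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- as.numeric(stats::coef(cv, s = lam))
  list(coefficients = setNames(beta, c("(Intercept)", colnames(x))),
       lambda = lam, cv = cv)
}

#' Fit the propensity model for amiodarone treatment
#'
#' Lasso-penalized logistic regression of the treatment indicator on the
#' encoded pre-hospital covariates. The penalty is selected by k-fold
#' cross-validated binomial deviance (folds stratified by treatment); the
#' intercept is unpenalized and continuous covariates are standardized
#' internally, with coefficients reported on the original scale. Fitted
#' probabilities are truncated to `[truncation, 1 - truncation]`.
#'
#' @param X encoded covariate matrix (rows = patients).
#' @param treatment 0/1 treatment indicator.
#' @param cv_folds number of CV folds for the penalty search.
#' @param seed integer seed for the fold assignment.
#' @param lambda_rule `"min"` (deviance-minimizing penalty, default) or
#'   `"1se"`.
#' @param lambda optional forced penalty; skips CV (use `0` for the
#'   unpenalized fit, a large value for the intercept-only fit).
#' @param truncation clamp for fitted probabilities, in `[0, 0.5)`.
#' @param nlambda,lambda_min_ratio resolution and depth of the candidate
#'   penalty path (solver defaults when `NULL`).
#' @return object of class `propensity_fit`: coefficients, selected penalty,
#'   truncated fitted probabilities `e_hat`, and settings.
#' @export
fit_propensity <- function(X, treatment, cv_folds = 10L, seed = 1L,
                           lambda_rule = c("min", "1se"), lambda = NULL,
                           truncation = 0.01, nlambda = 100L,
                           lambda_min_ratio = NULL) {
  treatment <- as.integer(treatment)
  if (length(unique(treatment)) < 2)
    stop_config("cannot estimate a propensity model: only one treatment arm present")
  if (nrow(X) < cv_folds && is.null(lambda))
    stop_config("fewer patients than CV folds")
  if (truncation < 0 || truncation >= 0.5)
    stop_config("truncation must lie in [0, 0.5)")
  res <- glmnet_logistic(X, treatment, cv_folds = cv_folds, seed = seed,
                         lambda_rule = match.arg(lambda_rule), lambda = lambda,
                         nlambda = nlambda, lambda_min_ratio = lambda_min_ratio)
  eta <- res$coefficients[1] + as.numeric(X %*% res$coefficients[-1])
  e_hat <- pmin(pmax(plogis(eta), truncation), 1 - truncation)
  structure(list(coefficients = res$coefficients, lambda = res$lambda,
                 e_hat = e_hat, cv_folds = cv_folds, seed = seed,
                 truncation = truncation,
                 lambda_rule = match.arg(lambda_rule)),
            class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, digits = 4, ...) {
  cat("Propensity model (lasso logistic), lambda =",
      signif(x$lambda, digits), "\n")
  nz <- x$coefficients[x$coefficients != 0]
  print(round(nz, digits))
  cat("fitted e(x): range", paste(signif(range(x$e_hat), 3), collapse = " - "),
      " truncation =", x$truncation, "\n")
  invisible(x)
}

#' @export
coef.propensity_fit <- function(object, ...) object$coefficients

#' @export
predict.propensity_fit <- function(object, newdata, ...) {
  eta <- object$coefficients[1] + as.numeric(newdata %*% object$coefficients[-1])
  pmin(pmax(plogis(eta), object$truncation), 1 - object$truncation)
}

#' Inverse-probability-of-treatment weights
#'
#' `w_i = 1 / (T_i * e_i + (1 - T_i) * (1 - e_i))`, the inverse probability of
#' the treatment actually received, with the propensity clamped to
#' `[truncation, 1 - truncation]` first. Since the denominator is a
#' probability, every weight is >= 1.
#'
#' @param fit a `propensity_fit`, or a numeric vector of propensities.
#' @param treatment 0/1 treatment indicator.
#' @param truncation clamp epsilon in `[0, 0.5)`; defaults to the fit's own.
#' @return numeric weight vector.
#' @export
compute_weights <- function(fit, treatment, truncation = NULL) {
  e <- if (inherits(fit, "propensity_fit")) {
    if (is.null(truncation)) truncation <- fit$truncation
    fit$e_hat
  } else as.numeric(fit)
  if (is.null(truncation)) truncation <- 0.01
  if (truncation < 0 || truncation >= 0.5)
    stop_config("truncation must lie in [0, 0.5)")
  e <- pmin(pmax(e, truncation), 1 - truncation)
  treatment <- as.numeric(treatment)
  1 / (treatment * e + (1 - treatment) * (1 - e))
}
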