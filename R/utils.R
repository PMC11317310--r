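#' @keywords internal
"_PACKAGE"

#' @importFrom stats plogis qlogis rnorm rlnorm rbinom runif quantile median
#'   glm binomial coef vcov qnorm pnorm predict as.formula setNames sd
#'   simulate
#' @importFrom utils read.csv write.csv
NULL

#' Round half away from zero
#'
#' Registry tables conventionally round 24.35 to 24.4; base [round()] rounds
#' half to even. Used for all displayed percentages.
#'
#' @param x numeric vector
#' @param digits decimal places to keep
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic child-seed derivation (MINSTD-style congruential step) so every
# stage draws from an independently seeded stream but the whole analysis is
# reproducible from one master seed. Products stay < 2^53, result in [1, 2^31-2].
derive_seed <- function(seed, key) {
  m <- 2147483647
  k <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271 + k) %% m
  s <- (s * 48271 + 11) %% m
  as.integer(s + 1)
}

# Evaluate expr under a local RNG state; the caller's .Random.seed is restored.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_config <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default analysis configuration
#'
#' One nested list drives every stage; all randomness is seeded from the single
#' master `seed` through a documented derivation, so permutation replicates can
#' re-run the whole pipeline from scratch reproducibly.
#'
#' @param seed master integer seed.
#' @param propensity list: `cv_folds`, `lambda_rule` ("min" or "1se"),
#'   `truncation` (propensity clamp epsilon).
#' @param benefit list: `cv_folds`, `lambda_rule`, `outcome` ("neuro" or
#'   "survival").
#' @param cv list: `outer_k`, `inner_k` for the nested cross-validation.
#' @param infer list: `bootstrap_B`, `perm_B`, `bootstrap_refit_full`.
#' @return a list of class `ohca_config`.
#' @export
ohca_config <- function(seed = 1L,
                        propensity = list(),
                        benefit = list(),
                        cv = list(),
                        infer = list()) {
  cfg <- list(
    seed = as.integer(seed),
    propensity = utils::modifyList(
      list(cv_folds = 10L, lambda_rule = "min", truncation = 0.01,
           nlambda = 100L, lambda_min_ratio = NULL), propensity),
    benefit = utils::modifyList(
      list(cv_folds = 10L, lambda_rule = "min", outcome = "neuro",
           nlambda = 100L, lambda_min_ratio = NULL), benefit),
    cv = utils::modifyList(list(outer_k = 5L, inner_k = 10L), cv),
    infer = utils::modifyList(
      list(bootstrap_B = 10000L, perm_B = 999L, bootstrap_refit_full = FALSE),
      infer)
  )
  class(cfg) <- "ohca_config"
  cfg
}
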