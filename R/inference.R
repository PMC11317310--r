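# Inference on differential treatment effect: unpenalized multivariate
# logistic model with a treatment-by-subgroup interaction, nonparametric
# bootstrap CI for the interaction OR, and a one-sided permutation test that
# re-runs every model-fitting stage from scratch under permuted treatment.

INTERACTION_TERMS <- c(X_COLS, "ecpr", "pci", "mth", "amiodarone", "subgroup",
                       "amiodarone_x_subgroup")

interaction_frame <- function(cohort, subgroup, outcome) {
  s <- as.integer(as.character(subgroup) == "benefit")
  df <- data.frame(cohort$X, check.names = FALSE)
  df$ecpr <- cohort$cointerventions[, "ecpr"]
  df$pci <- cohort$cointerventions[, "pci"]
  df$mth <- cohort$cointerventions[, "mth"]
  df$amiodarone <- cohort$T
  df$subgroup <- s
  df$amiodarone_x_subgroup <- cohort$T * s
  df$y <- cohort_outcome(cohort, outcome)
  df
}

#' Adjusted treatment-by-subgroup interaction model
#'
#' Unpenalized logistic regression of the 30-day outcome on the baseline
#' covariates used to derive the score, the in-hospital co-interventions
#' (ECPR, PCI, MTH), amiodarone, the score-defined subgroup, and the
#' amiodarone-by-subgroup product. The interaction odds ratio quantifies how
#' much larger the treatment odds ratio is in the predicted-benefit subgroup.
#'
#' @param cohort an `ohca_cohort`.
#' @param subgroup factor/character of `benefit` / `no_benefit` labels (e.g.
#'   the `subgroup` column of a [cross_validated_scores()] result).
#' @param outcome `"neuro"` or `"survival"`.
#' @param covariates adjustment covariates; defaults to the full published
#'   covariate set. A reduced set supports saturated toy analyses.
#' @return object of class `interaction_fit`: a table of odds ratios with
#'   95% Wald CIs, the interaction log-OR and its standard error, and a
#'   `separation` flag (set instead of failing when the MLE diverges).
#' @export
fit_interaction_model <- function(cohort, subgroup,
                                  outcome = c("neuro", "survival"),
                                  covariates = c(X_COLS, "ecpr", "pci", "mth")) {
  outcome <- match.arg(outcome)
  subgroup <- factor(as.character(subgroup), levels = c("no_benefit", "benefit"))
  if (length(subgroup) != n_patients(cohort))
    stop_config("subgroup labels must cover every patient")
  if (length(unique(subgroup)) < 2)
    stop_config("both subgroups must be non-empty")
  if (length(unique(cohort$T)) < 2)
    stop_config("both treatment arms must be non-empty")
  df <- interaction_frame(cohort, subgroup, outcome)
  terms <- c(covariates, "amiodarone", "subgroup", "amiodarone_x_subgroup")
  fml <- as.formula(paste("y ~", paste(terms, collapse = " + ")))
  fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
  cf <- coef(fit)[-1]                      # drop model intercept
  se_all <- rep(NA_real_, length(cf))
  names(se_all) <- names(cf)
  vc <- sqrt(diag(vcov(fit)))
  se_all[intersect(names(cf), names(vc))] <- vc[intersect(names(cf), names(vc))]
  se <- se_all
  # aliased (NA) adjustment covariates are dropped by glm and tolerated;
  # the fit only counts as separated when the estimates themselves diverge
  # or the interaction term is not estimable
  separation <- !fit$converged ||
    !is.finite(cf["amiodarone_x_subgroup"]) ||
    any(abs(cf) > 12, na.rm = TRUE) || any(se > 12, na.rm = TRUE)
  z <- qnorm(0.975)
  tab <- data.frame(term = names(cf), log_or = unname(cf), se = unname(se),
                    or = exp(unname(cf)),
                    ci_lo = exp(unname(cf) - z * unname(se)),
                    ci_hi = exp(unname(cf) + z * unname(se)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 interaction_log_or = unname(cf["amiodarone_x_subgroup"]),
                 interaction_se = unname(se["amiodarone_x_subgroup"]),
                 outcome = outcome, n = nrow(df), separation = separation,
                 glm_fit = fit),
            class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, digits = 3, ...) {
  cat("Treatment-by-subgroup interaction model (outcome:", x$outcome,
      ", n =", x$n, ")\n")
  if (x$separation) cat("WARNING: possible separation; estimates unreliable\n")
  tab <- x$table
  tab$or <- signif(tab$or, digits)
  tab$ci <- sprintf("(%.*f-%.*f)", digits - 1, tab$ci_lo, digits - 1, tab$ci_hi)
  print(tab[, c("term", "or", "ci")], row.names = FALSE)
  invisible(x)
}

#' @export
coef.interaction_fit <- function(object, ...) {
  setNames(object$table$log_or, object$table$term)
}

#' @export
summary.interaction_fit <- function(object, ...) object$table

#' Percentile bootstrap CI for the interaction odds ratio
#'
#' Resamples patients with replacement (each patient carries their subgroup
#' label) and refits the interaction model per replicate; the 2.5 and 97.5
#' percentiles of the replicate ORs form the interval. Replicates with
#' separation or non-finite estimates are dropped and counted. Optionally the
#' whole scoring pipeline (propensity, benefit score, nested CV, subgroup
#' assignment) is refit per replicate.
#'
#' @inheritParams fit_interaction_model
#' @param B number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param refit_full if `TRUE`, re-run the full pipeline per replicate
#'   (uses `config`); by default the fixed cross-validated labels are kept
#'   and only the interaction model is refit.
#' @param config an [ohca_config()], used when `refit_full = TRUE`.
#' @return list of class `boot_ci`: `ci` (OR scale), `point` (full-data OR),
#'   `stats` (replicate log-ORs), `B`, `n_dropped`, and `warning` when more
#'   than 20% of replicates were degenerate.
#' @export
bootstrap_ci <- function(cohort, subgroup, outcome = c("neuro", "survival"),
                         B = 10000L, seed = 1L, refit_full = FALSE,
                         config = ohca_config(),
                         covariates = c(X_COLS, "ecpr", "pci", "mth")) {
  outcome <- match.arg(outcome)
  if (B < 100) stop_config("B must be >= 100")
  n <- n_patients(cohort)
  point_fit <- fit_interaction_model(cohort, subgroup, outcome,
                                     covariates = covariates)
  subgroup <- factor(as.character(subgroup), levels = c("no_benefit", "benefit"))
  stats_v <- rep(NA_real_, B)
  with_seed(derive_seed(seed, "boot"), {
    idx_mat <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
  })
  for (b in seq_len(B)) {
    idx <- idx_mat[, b]
    boot_cohort <- subset_cohort(cohort, idx)
    lab <- subgroup[idx]
    if (refit_full) {
      cfg <- config
      cfg$seed <- derive_seed(seed, paste0("bootfit", b))
      sa <- try(cross_validated_scores(boot_cohort, config = cfg,
                                       outcome = outcome), silent = TRUE)
      if (inherits(sa, "try-error")) next
      lab <- sa$subgroup
    }
    fit <- try(fit_interaction_model(boot_cohort, lab, outcome,
                                     covariates = covariates), silent = TRUE)
    if (inherits(fit, "try-error") || fit$separation ||
        !is.finite(fit$interaction_log_or)) next
    stats_v[b] <- fit$interaction_log_or
  }
  ok <- stats_v[is.finite(stats_v)]
  n_dropped <- B - length(ok)
  warn <- NULL
  if (n_dropped > 0.2 * B)
    warn <- sprintf("%d of %d bootstrap replicates degenerate", n_dropped, B)
  ci <- if (length(ok)) unname(quantile(exp(ok), c(0.025, 0.975)))
        else c(NA_real_, NA_real_)
  structure(list(ci = ci, point = exp(point_fit$interaction_log_or),
                 stats = stats_v, B = B, n_dropped = n_dropped,
                 warning = warn, outcome = outcome),
            class = "boot_ci")
}

#' @export
print.boot_ci <- function(x, digits = 3, ...) {
  cat(sprintf("Interaction OR %.*f, 95%% percentile bootstrap CI (%.*f-%.*f), B = %d\n",
              digits, x$point, digits, x$ci[1], digits, x$ci[2], x$B))
  if (!is.null(x$warning)) cat("WARNING:", x$warning, "\n")
  invisible(x)
}

perm_pvalue <- function(observed, permuted) {
  (1 + sum(permuted >= observed)) / (1 + length(permuted))
}

# one full from-scratch pipeline pass: propensity -> weights -> benefit score
# -> nested-CV scoring -> subgroup at 0 -> interaction model
pipeline_interaction <- function(cohort, config, outcome, seed) {
  cfg <- config
  cfg$seed <- seed
  sa <- cross_validated_scores(cohort, config = cfg, outcome = outcome)
  fit <- fit_interaction_model(cohort, sa$subgroup, outcome)
  list(fit = fit, assignment = sa)
}

#' One-sided permutation test for the interaction
#'
#' Tests the alternative that amiodarone is beneficial in the positive-score
#' subgroup. For each permutation the treatment labels are randomly permuted
#' across patients and *all* model-fitting stages — propensity model,
#' weights, benefit score, nested-CV scoring, subgroup assignment, and the
#' interaction model — are re-run from scratch; the statistic is the
#' interaction log-OR and `p = (1 + #\{permuted >= observed\}) / (1 + B)`.
#'
#' With `early_stop_exceed = h` the sequential Monte Carlo rule is used:
#' permutation stops as soon as `h` permuted statistics reach the observed
#' one and `p = h / m` (m permutations done). Accept/reject decisions at any
#' `alpha <= h / (B + 1)` coincide with the fixed-B test, at a fraction of
#' the cost when the null is true.
#'
#' @inheritParams bootstrap_ci
#' @param B number of permutations (>= 19).
#' @param early_stop_exceed optional exceedance cap `h` (see above); `NULL`
#'   runs all `B` permutations.
#' @param max_redraw how many times a degenerate permuted fit may be redrawn
#'   before it counts as an exceedance (conservative).
#' @return object of class `perm_test`: `p`, `observed` (log-OR), `stats`
#'   (permuted log-ORs), `B_done`, `n_redrawn`, plus the observed
#'   `interaction_fit` and score assignment.
#' @export
permutation_test <- function(cohort, config = ohca_config(),
                             outcome = c("neuro", "survival"),
                             B = 999L, seed = 1L, early_stop_exceed = NULL,
                             max_redraw = 5L) {
  outcome <- match.arg(outcome)
  if (B < 19) stop_config("B must be >= 19")
  obs <- pipeline_interaction(cohort, config, outcome,
                              seed = derive_seed(seed, "obs"))
  if (obs$fit$separation || !is.finite(obs$fit$interaction_log_or))
    stop_config("observed interaction fit is degenerate")
  observed <- obs$fit$interaction_log_or
  n <- n_patients(cohort)
  stats_v <- numeric(0)
  n_redrawn <- 0L
  exceed <- 0L
  for (b in seq_len(B)) {
    stat <- NA_real_
    for (r in 0:max_redraw) {
      pseed <- derive_seed(seed, paste0("perm", b, "r", r))
      perm <- with_seed(pseed, sample.int(n))
      pc <- cohort
      pc$T <- cohort$T[perm]
      res <- try(pipeline_interaction(pc, config, outcome, seed = pseed),
                 silent = TRUE)
      if (!inherits(res, "try-error") && !res$fit$separation &&
          is.finite(res$fit$interaction_log_or)) {
        stat <- res$fit$interaction_log_or
        break
      }
      n_redrawn <- n_redrawn + 1L
    }
    if (is.na(stat)) stat <- Inf  # unresolvable replicate counts against H1
    stats_v <- c(stats_v, stat)
    exceed <- exceed + (stat >= observed)
    if (!is.null(early_stop_exceed) && exceed >= early_stop_exceed) break
  }
  m <- length(stats_v)
  p <- if (!is.null(early_stop_exceed) && exceed >= early_stop_exceed && m < B)
    early_stop_exceed / m
  else (1 + exceed) / (1 + B)
  structure(list(p = p, observed = observed, stats = stats_v, B = B,
                 B_done = m, n_redrawn = n_redrawn, seed = seed,
                 outcome = outcome, observed_fit = obs$fit,
                 assignment = obs$assignment),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, digits = 3, ...) {
  cat(sprintf("One-sided permutation test (outcome: %s): interaction OR %.*f, p = %.4g (%d permutations)\n",
              x$outcome, digits, exp(x$observed), x$p, x$B_done))
  invisible(x)
}

#' Outcome proportions by arm and subgroup
#'
#' 2 (treatment arm) x 2 (subgroup) tables of outcome proportions with
#' counts, for both 30-day outcomes.
#'
#' @inheritParams fit_interaction_model
#' @return list with, per outcome, `proportion`, `events` and `n` matrices
#'   (rows: amiodarone +/-; columns: benefit / no_benefit subgroup).
#' @export
subgroup_outcome_table <- function(cohort, subgroup) {
  subgroup <- factor(as.character(subgroup), levels = c("no_benefit", "benefit"))
  if (length(subgroup) != n_patients(cohort))
    stop_config("subgroup labels must cover every patient")
  arm <- factor(ifelse(cohort$T == 1, "amio_pos", "amio_neg"),
                levels = c("amio_pos", "amio_neg"))
  out <- lapply(c(neuro = "neuro", survival = "survival"), function(oc) {
    y <- cohort_outcome(cohort, oc)
    tab <- table(arm, subgroup)
    nmat <- matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
    emat <- tapply(y, list(arm, subgroup), sum)
    emat[is.na(emat)] <- 0
    emat <- matrix(as.numeric(emat), 2, 2, dimnames = dimnames(tab))
    pmat <- matrix(ifelse(nmat > 0, emat / nmat, NA_real_), 2, 2,
                   dimnames = dimnames(tab))
    list(proportion = pmat, events = emat, n = nmat)
  })
  structure(out, class = "subgroup_table")
}

#' @export
print.subgroup_table <- function(x, digits = 3, ...) {
  for (oc in names(x)) {
    cat("Outcome:", oc, "\n")
    print(round(x[[oc]]$proportion, digits))
  }
  invisible(x)
}
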