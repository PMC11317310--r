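# End-to-end orchestration: exclusions -> encoding -> developed score ->
# nested-CV subgroups -> interaction inference, with a serializable report.

#' Run the full subgroup-identification analysis
#'
#' Executes the whole pipeline on raw registry-style records (a data.frame, a
#' CSV path, or a [sim_config()] to simulate first): exclusion filters,
#' covariate encoding, the full-data "developed" benefit score, nested-CV
#' subgroup assignment, the adjusted interaction model, bootstrap CI and
#' (optionally) the from-scratch permutation test, for each requested
#' outcome. Every random stage is seeded from `config$seed` through a fixed
#' derivation, so reruns with the same input and config are identical.
#'
#' @param input data.frame of raw records, path to a cohort CSV, or a
#'   `sim_config`.
#' @param config an [ohca_config()].
#' @param outcomes character subset of `c("neuro", "survival")`.
#' @param run_permutation,run_bootstrap toggle the expensive inference
#'   stages (counts come from `config$infer`).
#' @return object of class `ohca_analysis`.
#' @export
run_ohca_analysis <- function(input, config = ohca_config(),
                              outcomes = c("neuro", "survival"),
                              run_permutation = TRUE, run_bootstrap = TRUE) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  records <- if (inherits(input, "sim_config")) generate_cohort(input)$records
             else if (is.character(input)) read_cohort_csv(input)
             else input
  val <- validate_input(records)
  if (nrow(val$violations) > 0)
    stop_config("input fails schema validation: ",
                val$violations$problem[1], " (column ",
                val$violations$column[1], ", row ", val$violations$row[1], ")")
  excl <- apply_exclusions(records)
  cohort <- excl$cohort
  summary_tab <- summarize_cohort(cohort)

  per_outcome <- lapply(setNames(outcomes, outcomes), function(oc) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("outcome_", oc))
    dev <- in_sample_scores(cohort, cfg, outcome = oc)
    sa <- cross_validated_scores(cohort, config = cfg, outcome = oc)
    split <- prop.table(table(sa$subgroup))
    outcome_tab <- subgroup_outcome_table(cohort, sa$subgroup)
    if (any(split == 0)) {
      # all patients on one side of the score cutoff: no interaction estimand
      return(list(developed = dev, cv_assignment = sa, subgroup_split = split,
                  outcome_table = outcome_tab, interaction = NULL,
                  bootstrap = NULL, permutation = NULL,
                  note = "degenerate subgroup split; inference skipped"))
    }
    ifit <- fit_interaction_model(cohort, sa$subgroup, oc)
    boot <- if (run_bootstrap)
      bootstrap_ci(cohort, sa$subgroup, oc, B = config$infer$bootstrap_B,
                   seed = derive_seed(cfg$seed, "boot"),
                   refit_full = config$infer$bootstrap_refit_full,
                   config = cfg)
    perm <- if (run_permutation)
      permutation_test(cohort, cfg, oc, B = config$infer$perm_B,
                       seed = derive_seed(cfg$seed, "perm"))
    list(developed = dev, cv_assignment = sa, subgroup_split = split,
         outcome_table = outcome_tab, interaction = ifit,
         bootstrap = boot, permutation = perm)
  })
  structure(list(tally = excl$tally, summary = summary_tab,
                 cohort = cohort, outcomes = per_outcome,
                 config = config,
                 version = as.character(utils::packageVersion("amioscore"))),
            class = "ohca_analysis")
}

#' @export
print.ohca_analysis <- function(x, ...) {
  cat("OHCA amiodarone subgroup analysis\n")
  cat("  records:", x$tally["total"], " retained:", x$tally["retained"],
      " excluded:", x$tally["total"] - x$tally["retained"], "\n")
  for (oc in names(x$outcomes)) {
    o <- x$outcomes[[oc]]
    sp <- o$subgroup_split
    if (is.null(o$interaction)) {
      cat(sprintf("  [%s] benefit subgroup: %.1f%% (%s)\n",
                  oc, 100 * sp["benefit"], o$note))
      next
    }
    cat(sprintf("  [%s] benefit subgroup: %.1f%%; interaction OR %.3f",
                oc, 100 * sp["benefit"], exp(o$interaction$interaction_log_or)))
    if (!is.null(o$bootstrap))
      cat(sprintf(" (95%% CI %.3f-%.3f)", o$bootstrap$ci[1], o$bootstrap$ci[2]))
    if (!is.null(o$permutation))
      cat(sprintf(", one-sided p = %.4g", o$permutation$p))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.ohca_analysis <- function(object, ...) {
  list(tally = object$tally,
       cohort_summary = object$summary,
       interaction = lapply(object$outcomes, function(o) o$interaction$table))
}

#' @export
plot.ohca_analysis <- function(x, outcome = names(x$outcomes)[1], ...) {
  sa <- x$outcomes[[outcome]]$cv_assignment
  graphics::hist(sa$cv_score, breaks = 40,
                 main = paste("Cross-validated benefit score (", outcome, ")"),
                 xlab = "score", col = "grey80", border = "white", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Writes the flow tally, the Table-1-style summary, the developed score
#' coefficients and penalties, subgroup splits, subgroup outcome tables, the
#' interaction OR tables, bootstrap CIs, permutation p-values, the config and
#' the package version.
#'
#' @param analysis an `ohca_analysis`.
#' @param path output JSON path.
#' @export
write_report_json <- function(analysis, path) {
  per_outcome <- lapply(analysis$outcomes, function(o) {
    list(
      developed_score = c(list(score_const = o$developed$model$beta0),
                          as.list(o$developed$model$beta)),
      lambda_propensity = o$developed$propensity$lambda,
      lambda_benefit = o$developed$model$lambda,
      subgroup_split = as.list(unclass(o$subgroup_split)),
      outcome_table = lapply(o$outcome_table, function(t)
        list(proportion = t$proportion, events = t$events, n = t$n)),
      interaction_or = o$interaction$table,
      interaction_separation = o$interaction$separation,
      bootstrap_ci = if (!is.null(o$bootstrap))
        list(point = o$bootstrap$point, ci = o$bootstrap$ci,
             B = o$bootstrap$B, dropped = o$bootstrap$n_dropped),
      permutation = if (!is.null(o$permutation))
        list(p = o$permutation$p, observed_log_or = o$permutation$observed,
             B = o$permutation$B, B_done = o$permutation$B_done)
    )
  })
  report <- list(
    flow_tally = as.list(analysis$tally),
    summary = list(continuous = analysis$summary$continuous,
                   categorical = analysis$summary$categorical),
    outcomes = per_outcome,
    config = unclass(analysis$config),
    version = analysis$version
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
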