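# Cohort construction: exclusion filters, covariate encoding, Table-1-style
# summaries, and CSV input/output for the registry data dictionary.

# canonical encoded covariate order; everything downstream keys off this
X_COLS <- c("age", "sex_male", "call_to_arrival_min", "cause_trauma",
            "witness", "bystander", "defib_1or2", "defib_3plus",
            "hypothermia", "prehosp_epi")

RAW_COLS <- c("patient_id", "age", "sex", "call_to_arrival_min", "cause_trauma",
              "witness", "bystander", "defib_category", "hypothermia_arrival",
              "prehosp_epi", "amiodarone", "ecpr", "pci", "mth",
              "cpc30", "survival30")

EXCLUSION_REASONS <- c("pediatric", "other_antiarrhythmic", "unlinkable",
                       "missing_data")

DEFIB_LEVELS <- c("0", "1_2", "3plus")

#' Encode raw covariates into the analysis design matrix
#'
#' Dummy-codes the pre-hospital candidate variables: defibrillation count uses
#' "0 times" as reference with indicators for 1-2 and >= 3 shocks; hypothermia
#' at hospital arrival is body temperature <= 34 C, with an unmeasurably low
#' temperature (coded `NA` in `body_temp_c`) counted as hypothermic. When a
#' `body_temp_c` column is present it takes precedence over any
#' `hypothermia_arrival` indicator; the raw temperature is not retained.
#'
#' @param records data.frame following the cohort data dictionary (see
#'   [read_cohort_csv()]).
#' @param standardize if `TRUE`, continuous columns (age, call-to-arrival
#'   minutes) are centered and scaled; the transform is returned so
#'   coefficients can be mapped back to the original scale.
#' @return list with `X` (numeric matrix, one row per record), and
#'   `transform` (`center`/`scale` vectors over all columns; identity when
#'   `standardize = FALSE`).
#' @export
encode_covariates <- function(records, standardize = FALSE) {
  bin <- function(col) {
    v <- records[[col]]
    if (is.logical(v)) v <- as.integer(v)
    bad <- !(v %in% c(0, 1))
    if (any(bad)) stop_config("column '", col, "' has values outside {0,1} at row ",
                              which(bad)[1])
    as.numeric(v)
  }
  dc <- as.character(records$defib_category)
  bad <- !(dc %in% DEFIB_LEVELS)
  if (any(bad)) stop_config("column 'defib_category' has unknown level '",
                            dc[which(bad)[1]], "' at row ", which(bad)[1])
  if ("body_temp_c" %in% names(records)) {
    bt <- records$body_temp_c
    hypo <- as.numeric(is.na(bt) | bt <= 34)
  } else {
    hypo <- bin("hypothermia_arrival")
  }
  X <- cbind(
    age = as.numeric(records$age),
    sex_male = bin("sex"),
    call_to_arrival_min = as.numeric(records$call_to_arrival_min),
    cause_trauma = bin("cause_trauma"),
    witness = bin("witness"),
    bystander = bin("bystander"),
    defib_1or2 = as.numeric(dc == "1_2"),
    defib_3plus = as.numeric(dc == "3plus"),
    hypothermia = hypo,
    prehosp_epi = bin("prehosp_epi")
  )
  ctr <- setNames(numeric(ncol(X)), colnames(X))
  scl <- setNames(rep(1, ncol(X)), colnames(X))
  if (standardize) {
    for (v in c("age", "call_to_arrival_min")) {
      ctr[v] <- mean(X[, v])
      s <- sd(X[, v])
      scl[v] <- if (is.na(s) || s == 0) 1 else s
      X[, v] <- (X[, v] - ctr[v]) / scl[v]
    }
  }
  list(X = X, transform = list(center = ctr, scale = scl))
}

as_analysis_cohort <- function(records) {
  enc <- encode_covariates(records, standardize = FALSE)
  structure(list(
    patient_id = records$patient_id,
    X = enc$X,
    T = as.integer(records$amiodarone),
    Y_neuro = as.integer(records$cpc30),
    Y_surv = as.integer(records$survival30),
    cointerventions = cbind(ecpr = as.numeric(records$ecpr),
                            pci = as.numeric(records$pci),
                            mth = as.numeric(records$mth))
  ), class = "ohca_cohort")
}

#' @export
print.ohca_cohort <- function(x, ...) {
  cat("Analysis cohort:", length(x$T), "patients;",
      sum(x$T), "amiodarone(+),", sum(1 - x$T), "amiodarone(-)\n")
  cat("  favorable neuro outcome:", sum(x$Y_neuro),
      " survival at 30 d:", sum(x$Y_surv), "\n")
  invisible(x)
}

n_patients <- function(cohort) length(cohort$T)

subset_cohort <- function(cohort, idx) {
  structure(list(
    patient_id = cohort$patient_id[idx],
    X = cohort$X[idx, , drop = FALSE],
    T = cohort$T[idx],
    Y_neuro = cohort$Y_neuro[idx],
    Y_surv = cohort$Y_surv[idx],
    cointerventions = cohort$cointerventions[idx, , drop = FALSE]
  ), class = "ohca_cohort")
}

cohort_outcome <- function(cohort, outcome = c("neuro", "survival")) {
  outcome <- match.arg(outcome)
  if (outcome == "neuro") cohort$Y_neuro else cohort$Y_surv
}

#' Apply the study exclusion criteria
#'
#' Drops records flagged as pediatric (< 18 years), treated with other
#' antiarrhythmic drugs, unlinkable to the pre-hospital Utstein data, or with
#' missing data, in that order: a record carrying several flags is tallied
#' once, under the first matching reason, so the tally is a disjoint partition
#' of the excluded records.
#'
#' @param records data.frame with the data-dictionary columns plus optional
#'   `exclusion_<reason>` 0/1 columns (`pediatric`, `other_antiarrhythmic`,
#'   `unlinkable`, `missing_data`). Absent flag columns count as all-zero.
#' @return list with `cohort` (an `ohca_cohort` of retained records) and
#'   `tally` (named counts per reason plus `retained` and `total`).
#' @export
apply_exclusions <- function(records) {
  n <- nrow(records)
  flags <- sapply(EXCLUSION_REASONS, function(r) {
    col <- paste0("exclusion_", r)
    if (col %in% names(records)) as.integer(records[[col]]) else integer(n)
  })
  if (n == 0) flags <- matrix(0L, 0, length(EXCLUSION_REASONS),
                              dimnames = list(NULL, EXCLUSION_REASONS))
  # first-matching-reason attribution
  reason <- apply(flags, 1, function(f) {
    i <- which(f == 1)
    if (length(i)) i[1] else 0L
  })
  if (n == 0) reason <- integer(0)
  tally <- setNames(
    vapply(seq_along(EXCLUSION_REASONS), function(i) sum(reason == i), 0L),
    EXCLUSION_REASONS)
  keep <- reason == 0L
  tally <- c(tally, retained = sum(keep), total = n)
  cohort <- if (any(keep)) as_analysis_cohort(records[keep, , drop = FALSE])
            else structure(list(patient_id = character(0),
                                X = matrix(numeric(0), 0, length(X_COLS),
                                           dimnames = list(NULL, X_COLS)),
                                T = integer(0), Y_neuro = integer(0),
                                Y_surv = integer(0),
                                cointerventions = matrix(numeric(0), 0, 3,
                                  dimnames = list(NULL, c("ecpr", "pci", "mth")))),
                           class = "ohca_cohort")
  list(cohort = cohort, tally = tally)
}

#' Summarize a cohort Table-1 style
#'
#' Medians with interquartile ranges for continuous variables and n (%) for
#' categorical variables and outcomes, split by amiodarone arm and overall.
#' Percentages are rounded half-up to one decimal, the registry-table
#' convention.
#'
#' @param cohort an `ohca_cohort`.
#' @return object of class `cohort_summary`: `$continuous` and `$categorical`
#'   data.frames plus arm sizes.
#' @export
summarize_cohort <- function(cohort) {
  arms <- list(amio_pos = cohort$T == 1, amio_neg = cohort$T == 0,
               overall = rep(TRUE, n_patients(cohort)))
  cont_vars <- c(age = "age", call_to_arrival_min = "call_to_arrival_min")
  cont <- do.call(rbind, lapply(names(cont_vars), function(v) {
    vals <- lapply(arms, function(a) cohort$X[a, v])
    data.frame(variable = v,
               median_pos = median(vals$amio_pos), q1_pos = unname(quantile(vals$amio_pos, .25)),
               q3_pos = unname(quantile(vals$amio_pos, .75)),
               median_neg = median(vals$amio_neg), q1_neg = unname(quantile(vals$amio_neg, .25)),
               q3_neg = unname(quantile(vals$amio_neg, .75)),
               median_all = median(vals$overall), q1_all = unname(quantile(vals$overall, .25)),
               q3_all = unname(quantile(vals$overall, .75)))
  }))
  cat_cols <- list(
    sex_male = cohort$X[, "sex_male"],
    cause_trauma = cohort$X[, "cause_trauma"],
    witness = cohort$X[, "witness"],
    bystander = cohort$X[, "bystander"],
    defib_0 = 1 - cohort$X[, "defib_1or2"] - cohort$X[, "defib_3plus"],
    defib_1or2 = cohort$X[, "defib_1or2"],
    defib_3plus = cohort$X[, "defib_3plus"],
    hypothermia = cohort$X[, "hypothermia"],
    prehosp_epi = cohort$X[, "prehosp_epi"],
    ecpr = cohort$cointerventions[, "ecpr"],
    pci = cohort$cointerventions[, "pci"],
    mth = cohort$cointerventions[, "mth"],
    survival_30d = cohort$Y_surv,
    neuro_cpc12_30d = cohort$Y_neuro
  )
  cat_tab <- do.call(rbind, lapply(names(cat_cols), function(v) {
    x <- cat_cols[[v]]
    row <- data.frame(variable = v)
    for (a in names(arms)) {
      sel <- arms[[a]]
      nn <- sum(x[sel])
      pct <- if (sum(sel) == 0) NA_real_ else round_half_up(100 * nn / sum(sel), 1)
      row[[paste0("n_", a)]] <- nn
      row[[paste0("pct_", a)]] <- pct
    }
    row
  }))
  structure(list(continuous = cont, categorical = cat_tab,
                 n = vapply(arms, sum, 0L)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: amiodarone(+) n = %d, amiodarone(-) n = %d, overall n = %d\n\n",
              x$n["amio_pos"], x$n["amio_neg"], x$n["overall"]))
  for (i in seq_len(nrow(x$continuous))) {
    r <- x$continuous[i, ]
    cat(sprintf("%-22s %6.1f (%.1f-%.1f) | %6.1f (%.1f-%.1f) | %6.1f (%.1f-%.1f)\n",
                r$variable, r$median_pos, r$q1_pos, r$q3_pos,
                r$median_neg, r$q1_neg, r$q3_neg,
                r$median_all, r$q1_all, r$q3_all))
  }
  cat("\n")
  for (i in seq_len(nrow(x$categorical))) {
    r <- x$categorical[i, ]
    cat(sprintf("%-22s %5d (%5.1f) | %5d (%5.1f) | %5d (%5.1f)\n",
                r$variable, r$n_amio_pos, r$pct_amio_pos,
                r$n_amio_neg, r$pct_amio_neg, r$n_overall, r$pct_overall))
  }
  invisible(x)
}

#' Read / write cohort CSV files
#'
#' The data dictionary (bit-exact column names): `patient_id, age, sex,
#' call_to_arrival_min, cause_trauma, witness, bystander, defib_category,
#' hypothermia_arrival, prehosp_epi, amiodarone, ecpr, pci, mth, cpc30,
#' survival30`, plus optional `exclusion_*` flag columns. Yes/no variables are
#' coded 1/0; `defib_category` takes values `0`, `1_2`, `3plus`.
#'
#' @param path file path.
#' @param records data.frame of raw cohort records.
#' @return `read_cohort_csv` returns the records data.frame;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(defib_category = "character"))
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate an input table against the cohort data dictionary
#'
#' Report-only schema check: missing columns, non-binary codes, unknown
#' defibrillation categories, non-numeric or missing continuous values, and a
#' missingness census. Nothing is fitted and no error is thrown.
#'
#' @param input path to a CSV file or a data.frame.
#' @return list with `violations` (data.frame: column, row, problem) and
#'   `missing_census` (named count of `NA`s per column); class
#'   `cohort_validation`.
#' @export
validate_input <- function(input) {
  records <- if (is.character(input)) read_cohort_csv(input) else input
  viol <- list()
  add <- function(column, row, problem)
    viol[[length(viol) + 1]] <<- data.frame(column = column, row = row,
                                            problem = problem)
  if (nrow(records) == 0) add(NA_character_, NA_integer_, "no records")
  for (col in setdiff(RAW_COLS, names(records)))
    add(col, NA_integer_, "missing column")
  binary_cols <- intersect(c("sex", "cause_trauma", "witness", "bystander",
                             "hypothermia_arrival", "prehosp_epi", "amiodarone",
                             "ecpr", "pci", "mth", "cpc30", "survival30"),
                           names(records))
  for (col in binary_cols) {
    bad <- which(!is.na(records[[col]]) & !(records[[col]] %in% c(0, 1)))
    for (r in bad) add(col, r, paste0("invalid code '", records[[col]][r], "'"))
  }
  if ("defib_category" %in% names(records)) {
    dc <- as.character(records$defib_category)
    bad <- which(!is.na(dc) & !(dc %in% DEFIB_LEVELS))
    for (r in bad) add("defib_category", r, paste0("invalid code '", dc[r], "'"))
  }
  for (col in intersect(c("age", "call_to_arrival_min"), names(records))) {
    if (!is.numeric(records[[col]]))
      add(col, NA_integer_, "non-numeric")
    else {
      bad <- which(!is.na(records[[col]]) & records[[col]] < 0)
      for (r in bad) add(col, r, "negative value")
    }
  }
  census <- vapply(records, function(v) sum(is.na(v)), 0L)
  violations <- if (length(viol)) do.call(rbind, viol)
                else data.frame(column = character(0), row = integer(0),
                                problem = character(0))
  structure(list(violations = violations, missing_census = census,
                 n_records = nrow(records)),
            class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("Input validation:", x$n_records, "records,",
      nrow(x$violations), "violation(s)\n")
  if (nrow(x$violations)) print(x$violations)
  miss <- x$missing_census[x$missing_census > 0]
  if (length(miss)) {
    cat("Missing values:\n")
    print(miss)
  }
  invisible(x)
}
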