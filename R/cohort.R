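#' Select case patients with censoring at first target diagnosis
#'
#' A patient is a case when they carry at least `min_dx` diagnoses of the
#' target code within the window AND appear in the catastrophic-illness
#' registry (the registry confirms the clinical diagnosis; claims codes
#' alone are not sufficient). A case's history is censored at the first
#' target diagnosis: only non-target records strictly before that date
#' are kept, so the model only ever sees pre-diagnosis data.
#'
#' @param records Clean, normalized `diag_records` (see [filter_noise()]).
#' @param registry Character vector of registry-confirmed patient IDs.
#' @param target_code Five-character target diagnosis code (e.g. `"71400"`
#'   for rheumatoid arthritis).
#' @param min_dx Minimum number of target-code diagnoses (default 2).
#' @param window Length-2 Date vector; records outside it are ignored.
#' @return Named list of `patient_history` objects, one per case. Each has
#'   `patient_id`, `label = "case"`, `records` (date-ordered, censored)
#'   and `censor_date` (date of first target diagnosis).
#' @export
select_cases <- function(records, registry, target_code, min_dx = 2L,
                         window = as.Date(c("2000-01-01", "2008-12-31"))) {
  if (length(registry) == 0L) warning("empty registry: zero cases selected")
  window <- as.Date(window)
  records <- records[records$visit_date >= window[1L] &
                       records$visit_date <= window[2L], , drop = FALSE]
  is_target <- records$code5 == target_code
  tgt <- records[is_target, , drop = FALSE]
  n_dx <- table(tgt$patient_id)
  eligible <- names(n_dx)[n_dx >= min_dx]
  case_ids <- sort(intersect(eligible, registry))

  by_patient <- split(records[records$patient_id %in% case_ids, ,
                              drop = FALSE],
                      records$patient_id[records$patient_id %in% case_ids])
  out <- lapply(case_ids, function(pid) {
    mine <- by_patient[[pid]]
    censor <- min(mine$visit_date[mine$code5 == target_code])
    kept <- mine[mine$visit_date < censor & mine$code5 != target_code, ,
                 drop = FALSE]
    kept <- kept[order(kept$visit_date, kept$code5), , drop = FALSE]
    rownames(kept) <- NULL
    patient_history(pid, "case", kept, censor_date = censor)
  })
  names(out) <- case_ids
  out
}

#' Select control patients
#'
#' Controls are patients with at least one record in the window, zero
#' target-code diagnoses, and who are not cases. Patients with
#' target-code evidence below the case threshold are excluded from both
#' arms: they are neither confirmed cases nor clean controls, and letting
#' them into the control arm would contaminate the labels.
#'
#' @param records Clean, normalized `diag_records`.
#' @param case_ids Character vector of selected case patient IDs.
#' @param target_code Five-character target diagnosis code.
#' @param window Length-2 Date vector.
#' @return Named list of `patient_history` objects with `label =
#'   "control"` and full-window histories (`censor_date` absent).
#' @export
select_controls <- function(records, case_ids, target_code,
                            window = as.Date(c("2000-01-01", "2008-12-31"))) {
  window <- as.Date(window)
  records <- records[records$visit_date >= window[1L] &
                       records$visit_date <= window[2L], , drop = FALSE]
  tainted <- unique(records$patient_id[records$code5 == target_code])
  all_ids <- unique(records$patient_id)
  ctrl_ids <- sort(setdiff(all_ids, union(tainted, case_ids)))
  by_patient <- split(records[records$patient_id %in% ctrl_ids, ,
                              drop = FALSE],
                      records$patient_id[records$patient_id %in% ctrl_ids])
  out <- lapply(ctrl_ids, function(pid) {
    mine <- by_patient[[pid]]
    mine <- mine[order(mine$visit_date, mine$code5), , drop = FALSE]
    rownames(mine) <- NULL
    patient_history(pid, "control", mine, censor_date = NULL)
  })
  names(out) <- ctrl_ids
  out
}

patient_history <- function(patient_id, label, records, censor_date = NULL) {
  structure(list(patient_id = patient_id, label = label,
                 records = records, censor_date = censor_date),
            class = "patient_history")
}

#' Assemble a case-control cohort
#'
#' Runs [select_cases()] then [select_controls()] and bundles the two arms
#' with a selection log recording counts at each step of the enrolment
#' flow.
#'
#' @inheritParams select_cases
#' @return A `risk_cohort` list with `cases`, `controls`, `target_code`,
#'   `window` and `selection_log`.
#' @export
build_cohort <- function(records, registry, target_code, min_dx = 2L,
                         window = as.Date(c("2000-01-01", "2008-12-31"))) {
  window <- as.Date(window)
  cases <- select_cases(records, registry, target_code, min_dx, window)
  controls <- select_controls(records, names(cases), target_code, window)
  in_win <- records$visit_date >= window[1L] & records$visit_date <= window[2L]
  log <- list(
    patients_with_records = length(unique(records$patient_id[in_win])),
    cases = length(cases),
    controls = length(controls),
    excluded_subthreshold_target =
      length(unique(records$patient_id[in_win])) -
        length(cases) - length(controls)
  )
  structure(list(cases = cases, controls = controls,
                 target_code = target_code, window = window,
                 selection_log = log),
            class = "risk_cohort")
}

#' @export
print.risk_cohort <- function(x, ...) {
  cat("Case-control cohort (target", x$target_code, ")\n")
  cat("  cases:   ", length(x$cases), "\n")
  cat("  controls:", length(x$controls), "\n")
  cat("  window:  ", format(x$window[1]), "to", format(x$window[2]), "\n")
  invisible(x)
}

#' Cohort prevalence
#'
#' @param n_cases,n_controls Arm sizes.
#' @return Prevalence of the case class as a percentage,
#'   `100 * n_cases / (n_cases + n_controls)`.
#' @export
cohort_prevalence <- function(n_cases, n_controls) {
  100 * n_cases / (n_cases + n_controls)
}

#' Descriptive cohort summary with between-arm tests
#'
#' Per-arm mean and SD of per-year record counts, visit counts (distinct
#' visit dates) and distinct-code counts, with Student two-sample t
#' statistics for the continuous rows; female proportion with a Pearson
#' chi-squared statistic when a `sex` lookup is supplied; and the cohort
#' prevalence. With a single-arm cohort the summary is produced without
#' test statistics.
#'
#' @param cohort A `risk_cohort`.
#' @param sex Optional named character vector mapping patient_id to
#'   `"F"`/`"M"`.
#' @return A `cohort_summary` list with `prevalence_pct`, a `continuous`
#'   data.frame (variable, case_mean, case_sd, control_mean, control_sd,
#'   t, p) and optionally a `proportions` data.frame.
#' @export
summarize_cohort <- function(cohort, sex = NULL) {
  years <- as.numeric(diff(cohort$window)) / 365.25
  per_patient <- function(h) {
    c(records_per_year = nrow(h$records) / years,
      visits_per_year = length(unique(h$records$visit_date)) / years,
      distinct_codes = length(unique(h$records$code5)))
  }
  arm_stats <- function(arm) {
    if (length(arm) == 0L) return(NULL)
    do.call(rbind, lapply(arm, per_patient))
  }
  ca <- arm_stats(cohort$cases)
  co <- arm_stats(cohort$controls)
  both <- !is.null(ca) && !is.null(co)

  vars <- c("records_per_year", "visits_per_year", "distinct_codes")
  cont <- data.frame(
    variable = vars,
    case_mean = if (!is.null(ca)) colMeans(ca)[vars] else NA_real_,
    case_sd = if (!is.null(ca)) apply(ca, 2, stats::sd)[vars] else NA_real_,
    control_mean = if (!is.null(co)) colMeans(co)[vars] else NA_real_,
    control_sd = if (!is.null(co)) apply(co, 2, stats::sd)[vars] else NA_real_,
    t = NA_real_, p = NA_real_, row.names = NULL
  )
  if (both && nrow(ca) > 1L && nrow(co) > 1L) {
    for (i in seq_along(vars)) {
      if (stats::sd(ca[, i]) == 0 && stats::sd(co[, i]) == 0) {
        # degenerate: identical-variance-zero arms; t is 0 when means agree
        cont$t[i] <- if (mean(ca[, i]) == mean(co[, i])) 0 else Inf
        next
      }
      tt <- stats::t.test(ca[, i], co[, i], var.equal = TRUE)
      cont$t[i] <- unname(tt$statistic)
      cont$p[i] <- tt$p.value
    }
  }

  props <- NULL
  if (!is.null(sex)) {
    f_case <- sum(sex[names(cohort$cases)] == "F", na.rm = TRUE)
    f_ctrl <- sum(sex[names(cohort$controls)] == "F", na.rm = TRUE)
    n_case <- length(cohort$cases); n_ctrl <- length(cohort$controls)
    tab <- rbind(c(f_case, n_case - f_case), c(f_ctrl, n_ctrl - f_ctrl))
    chi <- NA_real_; p <- NA_real_
    if (both && all(rowSums(tab) > 0)) {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      chi <- unname(ct$statistic); p <- ct$p.value
    }
    props <- data.frame(
      variable = "female_proportion",
      case_value = f_case / n_case, control_value = f_ctrl / n_ctrl,
      chisq = chi, p = p
    )
  }

  structure(list(
    prevalence_pct = cohort_prevalence(length(cohort$cases),
                                       length(cohort$controls)),
    continuous = cont,
    proportions = props
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Prevalence: %.4g%%\n", x$prevalence_pct))
  print(x$continuous, digits = 3)
  if (!is.null(x$proportions)) print(x$proportions, digits = 3)
  invisible(x)
}

#' Read a registry file (one patient ID per line)
#'
#' @param path Path to the registry text file.
#' @return Character vector of patient IDs.
#' @export
read_registry <- function(path) {
  ids <- readLines(path, encoding = "UTF-8", warn = FALSE)
  ids[nzchar(trimws(ids))]
}
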