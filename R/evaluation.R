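#' Stratified k-fold assignment
#'
#' Assigns each patient to one of k folds so that every fold carries an
#' (almost) equal share of each class: within each class, patients are
#' shuffled under the seed and dealt round-robin, so per-class fold
#' counts differ by at most one. The assignment is deterministic given
#' the labels, k and seed.
#'
#' @param labels Per-patient class labels.
#' @param k Fold count (>= 2).
#' @param seed Integer seed.
#' @return Integer vector in `1..k`, one entry per patient.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k = ", k, " exceeds the number of patients (", n, ")")
  labels <- as.character(labels)
  fold <- integer(n)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  fold
}

#' Confusion metrics for one evaluation
#'
#' Computes sensitivity `TP / CP` (the share of true cases assessed as
#' cases; equivalent to recall), specificity `TN / CN` (the share of
#' true controls assessed as controls) and accuracy
#' `(TP + TN) / (CP + CN)`. With balanced classes (`CP == CN`) accuracy
#' equals the average of sensitivity and specificity. A metric whose
#' denominator is zero is returned as `NA` and flagged in `undefined`,
#' never silently reported as zero.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param positive The case-class label (default `"case"`).
#' @return A `fold_metrics` list with counts `true_positive`,
#'   `true_negative`, `condition_positive`, `condition_negative` and
#'   proportions `sensitivity`, `specificity`, `accuracy`, plus
#'   `undefined` naming any metric with a zero denominator.
#' @export
compute_metrics <- function(truth, predicted, positive = "case") {
  stopifnot(length(truth) == length(predicted))
  truth <- as.character(truth); predicted <- as.character(predicted)
  is_pos <- truth == positive
  tp <- sum(is_pos & predicted == positive)
  tn <- sum(!is_pos & predicted != positive)
  cp <- sum(is_pos); cn <- sum(!is_pos)
  undefined <- character()
  if (cp == 0L) undefined <- c(undefined, "sensitivity")
  if (cn == 0L) undefined <- c(undefined, "specificity")
  structure(list(
    true_positive = tp, true_negative = tn,
    condition_positive = cp, condition_negative = cn,
    sensitivity = if (cp > 0L) tp / cp else NA_real_,
    specificity = if (cn > 0L) tn / cn else NA_real_,
    accuracy = if (cp + cn > 0L) (tp + tn) / (cp + cn) else NA_real_,
    undefined = undefined
  ), class = "fold_metrics")
}

#' Population standard deviation
#'
#' The variation measure used for fold-to-fold stability: the square
#' root of the mean squared deviation from the mean (divide by N, not
#' N - 1).
#'
#' @param x Numeric vector.
#' @return Nonnegative scalar.
#' @export
population_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

#' Aggregate per-fold metrics
#'
#' Macro-averages the per-fold metric values: means are arithmetic means
#' across folds and SDs are population SDs ([population_sd()]), the
#' stability measure for the classifier.
#'
#' @param per_fold List of `fold_metrics`.
#' @param seed Seed recorded for provenance (optional).
#' @return An `eval_result` list: `per_fold`, `mean` and `sd` (each with
#'   `sensitivity`, `specificity`, `accuracy`), `n_folds`, `seed`.
#' @export
aggregate_metrics <- function(per_fold, seed = NULL) {
  stopifnot(length(per_fold) > 0)
  pull <- function(name) {
    vapply(per_fold, function(m) m[[name]], numeric(1))
  }
  metrics <- c("sensitivity", "specificity", "accuracy")
  structure(list(
    per_fold = per_fold,
    mean = lapply(stats::setNames(metrics, metrics),
                  function(m) mean(pull(m), na.rm = TRUE)),
    sd = lapply(stats::setNames(metrics, metrics),
                function(m) population_sd(pull(m))),
    n_folds = length(per_fold),
    seed = seed
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("%d-fold evaluation:\n", x$n_folds))
  for (m in c("sensitivity", "specificity", "accuracy")) {
    cat(sprintf("  %-12s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Cross-validated risk assessment
#'
#' Runs the full assessment protocol on a labelled patient-disease
#' matrix: stratified k-fold split, factorization at rank R, classifier
#' training on the training loadings, prediction on held-out patients,
#' and per-fold confusion metrics.
#'
#' Two factorization protocols are supported. In `"inductive"` mode
#' (the default) the factors are fitted on the training folds only and
#' held-out rows are projected by [fold_in()], so no test information
#' reaches the factor space. In `"transductive"` mode the whole matrix
#' is factorized once and the cross-validation splits only the classifier
#' stage — the historical protocol for this pipeline; its factor space
#' has seen the test rows, which flatters no labels but does share
#' unlabeled structure.
#'
#' @param pdm A `pd_matrix` (labels must contain both arms), or a plain
#'   matrix together with `labels`.
#' @param R Factor count.
#' @param folds Fold count (default 10).
#' @param seed Base seed: folds, factorizations and fold-ins all derive
#'   from it.
#' @param mode `"inductive"` or `"transductive"`.
#' @param C,gamma Classifier parameters (defaults `2`, `0.03125`).
#' @param labels Optional label vector when `pdm` is a bare matrix.
#' @param max_iter,tol Factorization controls passed to [nmf_fit()].
#' @param pooled Also compute pooled metrics over the concatenated
#'   held-out predictions (stored as `pooled` on the result).
#' @return An `eval_result` (see [aggregate_metrics()]).
#' @export
run_cv <- function(pdm, R, folds = 10L, seed = 1L,
                   mode = c("inductive", "transductive"),
                   C = 2, gamma = 0.03125, labels = NULL,
                   max_iter = 300L, tol = 1e-5, pooled = FALSE) {
  mode <- match.arg(mode)
  if (inherits(pdm, "pd_matrix")) {
    labels <- pdm$labels
    X <- pdm$PD
  } else {
    if (is.null(labels)) stop("labels required with a bare matrix")
    X <- pdm
  }
  labels <- as.character(labels)
  fold_id <- stratified_kfold(labels, k = folds, seed = seed)

  full_fit <- NULL
  if (mode == "transductive") {
    full_fit <- nmf_fit(X, R = R, seed = seed + 1000L,
                        max_iter = max_iter, tol = tol)
  }
  per_fold <- vector("list", folds)
  all_truth <- character(); all_pred <- character()
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    te <- !tr
    if (mode == "inductive") {
      fit <- nmf_fit(X[tr, , drop = FALSE], R = R,
                     seed = seed + 1000L + f, max_iter = max_iter,
                     tol = tol)
      feat_tr <- fit$PR
      feat_te <- fold_in(X[te, , drop = FALSE], fit$DR,
                         seed = seed + 2000L + f)
    } else {
      feat_tr <- full_fit$PR[tr, , drop = FALSE]
      feat_te <- full_fit$PR[te, , drop = FALSE]
    }
    model <- train_classifier(feat_tr, labels[tr], C = C, gamma = gamma)
    pred <- predict_risk(model, feat_te)
    per_fold[[f]] <- compute_metrics(labels[te], pred$label)
    if (pooled) {
      all_truth <- c(all_truth, labels[te])
      all_pred <- c(all_pred, pred$label)
    }
  }
  out <- aggregate_metrics(per_fold, seed = seed)
  if (pooled) out$pooled <- compute_metrics(all_truth, all_pred)
  out
}

#' Grouped-control evaluation
#'
#' Evaluation design for heavily imbalanced cohorts: the controls are
#' partitioned into `n_groups` disjoint groups of `group_size`, and the
#' protocol is run once per group on the full case set plus that group's
#' controls (each run sees the same cases but different controls). The
#' conventional configuration is 50 groups of 500 controls.
#'
#' @param pdm A `pd_matrix` containing all cases and controls.
#' @param n_groups Number of disjoint control groups.
#' @param group_size Controls per group; `n_groups * group_size` must not
#'   exceed the number of controls.
#' @param protocol Function `(pd_matrix, seed) -> eval_result` run on
#'   each case+group matrix (default wraps [run_cv()]).
#' @param seed Seed for the control partition and the per-group protocol
#'   seeds.
#' @param ... Passed to the default protocol's [run_cv()] call.
#' @return List with `results` (one `eval_result` per group) and
#'   `grand` (mean and population SD of the group means for each
#'   metric).
#' @export
grouped_control_evaluation <- function(pdm, n_groups = 50L,
                                       group_size = 500L,
                                       protocol = NULL, seed = 1L, ...) {
  ctrl_idx <- which(pdm$labels == "control")
  case_idx <- which(pdm$labels == "case")
  if (n_groups * group_size > length(ctrl_idx)) {
    stop("need ", n_groups * group_size, " controls, have ",
         length(ctrl_idx))
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  shuffled <- ctrl_idx[sample.int(length(ctrl_idx))]
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  groups <- split(shuffled[seq_len(n_groups * group_size)],
                  rep(seq_len(n_groups), each = group_size))
  if (is.null(protocol)) {
    protocol <- function(sub_pdm, seed) run_cv(sub_pdm, seed = seed, ...)
  }
  results <- lapply(seq_len(n_groups), function(g) {
    idx <- c(case_idx, groups[[g]])
    sub <- pd_matrix(pdm$PD[idx, , drop = FALSE], pdm$row_ids[idx],
                     pdm$col_codes, pdm$labels[idx])
    protocol(sub, seed = seed + g)
  })
  metrics <- c("sensitivity", "specificity", "accuracy")
  grand_mean <- lapply(stats::setNames(metrics, metrics), function(m) {
    mean(vapply(results, function(r) r$mean[[m]], numeric(1)))
  })
  grand_sd <- lapply(stats::setNames(metrics, metrics), function(m) {
    population_sd(vapply(results, function(r) r$mean[[m]], numeric(1)))
  })
  list(results = results, grand = list(mean = grand_mean, sd = grand_sd),
       groups = groups)
}

#' Serialize an evaluation result as YAML + per-fold CSV
#'
#' @param result An `eval_result`.
#' @param yaml_path Output YAML path (means, SDs, fold count, seed).
#' @param csv_path Optional per-fold CSV path.
#' @export
write_eval_result <- function(result, yaml_path, csv_path = NULL) {
  yaml::write_yaml(list(
    n_folds = result$n_folds, seed = result$seed,
    mean = result$mean, sd = result$sd
  ), yaml_path)
  if (!is.null(csv_path)) {
    df <- do.call(rbind, lapply(seq_along(result$per_fold), function(i) {
      m <- result$per_fold[[i]]
      data.frame(fold = i, true_positive = m$true_positive,
                 true_negative = m$true_negative,
                 condition_positive = m$condition_positive,
                 condition_negative = m$condition_negative,
                 sensitivity = m$sensitivity,
                 specificity = m$specificity, accuracy = m$accuracy)
    }))
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(yaml_path)
}
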