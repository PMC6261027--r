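#' Train the disease risk classifier
#'
#' Fits a soft-margin support vector machine with a radial-basis-function
#' kernel on patient loading vectors (rows of `PR`). The defaults
#' `C = 2`, `gamma = 0.03125` are the grid-search-selected operating
#' point for this feature space; both are exposed for re-tuning on new
#' cohorts via [grid_search()].
#'
#' @param features N x R nonnegative feature matrix (patient loadings).
#' @param labels Per-row class labels (`"case"`/`"control"`, or any
#'   2-level factor); both classes must be present.
#' @param C Misclassification-cost parameter (> 0).
#' @param gamma RBF kernel-width parameter (> 0).
#' @return A `risk_model` list wrapping the fitted classifier with its
#'   parameters.
#' @export
train_classifier <- function(features, labels, C = 2, gamma = 0.03125) {
  stopifnot(C > 0, gamma > 0)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) {
    stop("both classes must be present in the training labels")
  }
  if (nrow(features) != length(labels)) {
    stop("one label per feature row required")
  }
  fit <- e1071::svm(x = as.matrix(features), y = labels,
                    type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE)
  structure(list(classifier = fit, C = C, gamma = gamma,
                 levels = levels(labels), R = ncol(features)),
            class = "risk_model")
}

#' Predict disease risk for unseen patients
#'
#' @param model A `risk_model` from [train_classifier()].
#' @param features n x R feature matrix; the column count must match the
#'   training feature dimension.
#' @return A data.frame with one row per input row: `label` (predicted
#'   class) and `score` (signed distance from the separating surface;
#'   positive values favour the first training class level).
#' @export
predict_risk <- function(model, features) {
  features <- as.matrix(features)
  if (nrow(features) == 0L) {
    return(data.frame(label = character(), score = numeric()))
  }
  if (ncol(features) != model$R) {
    stop("feature dimension ", ncol(features),
         " does not match training dimension ", model$R)
  }
  pred <- stats::predict(model$classifier, features, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  data.frame(label = as.character(pred), score = as.numeric(dv[, 1L]),
             stringsAsFactors = FALSE)
}

#' Grid search for the classifier parameters
#'
#' Exhaustively evaluates every (C, gamma) pair by inner k-fold
#' cross-validated accuracy and returns the arg-max pair. Ties are broken
#' toward the smaller C, then the smaller gamma (the least complex
#' model). Default grids are the conventional powers-of-two sweep,
#' C in 2^(-5..15) and gamma in 2^(-15..3).
#'
#' @param features,labels As in [train_classifier()].
#' @param C_grid,gamma_grid Numeric candidate vectors.
#' @param folds Inner CV fold count (default 5).
#' @param seed Seed for the inner fold assignment.
#' @return List with `C`, `gamma` and `cv_table` (one row per pair with
#'   its mean inner-CV accuracy).
#' @export
grid_search <- function(features, labels,
                        C_grid = 2^seq(-5, 15, by = 2),
                        gamma_grid = 2^seq(-15, 3, by = 2),
                        folds = 5L, seed = 1L) {
  stopifnot(length(C_grid) > 0, length(gamma_grid) > 0)
  labels <- factor(labels)
  features <- as.matrix(features)
  fold_id <- stratified_kfold(labels, k = folds, seed = seed)
  grid <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid))
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    fold_acc <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f; te <- !tr
      model <- train_classifier(features[tr, , drop = FALSE], labels[tr],
                                C = grid$C[g], gamma = grid$gamma[g])
      mean(predict_risk(model, features[te, , drop = FALSE])$label ==
             as.character(labels[te]))
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  grid$accuracy <- acc
  # arg-max with ties toward smaller C then smaller gamma
  ord <- order(-grid$accuracy, grid$C, grid$gamma)
  best <- grid[ord[1L], ]
  list(C = best$C, gamma = best$gamma, cv_table = grid)
}

#' Sweep the factor count R
#'
#' For each candidate R the matrix is factorized and evaluated by
#' stratified k-fold cross-validation, recording mean sensitivity,
#' specificity and accuracy, the accuracy SD, and the
#' sensitivity-specificity gap. Candidates with `R >= M` are flagged
#' invalid (the factorization would not reduce the dimension).
#'
#' @param pdm A `pd_matrix` with both arms labelled.
#' @param R_values Candidate factor counts; the conventional sweep for
#'   full-scale cohorts is `seq(100, 900, by = 100)`.
#' @param folds CV fold count (default 10).
#' @param seed Base seed for folds and factorizations.
#' @param mode `"inductive"` (fit factors on training folds, fold in test
#'   rows) or `"transductive"` (factorize once up front).
#' @param C,gamma Classifier parameters.
#' @param ... Further arguments to [run_cv()] (e.g. `max_iter`).
#' @return A data.frame of sweep rows: `R`, `mean_sensitivity`,
#'   `mean_specificity`, `mean_accuracy`, `sd_accuracy`, `gap`, `valid`.
#' @export
sweep_R <- function(pdm, R_values = seq(100, 900, by = 100), folds = 10L,
                    seed = 1L, mode = c("inductive", "transductive"),
                    C = 2, gamma = 0.03125, ...) {
  mode <- match.arg(mode)
  M <- ncol(pdm$PD)
  rows <- lapply(R_values, function(R) {
    if (R >= M) {
      return(data.frame(R = R, mean_sensitivity = NA_real_,
                        mean_specificity = NA_real_,
                        mean_accuracy = NA_real_, sd_accuracy = NA_real_,
                        gap = NA_real_, valid = FALSE))
    }
    res <- run_cv(pdm, R = R, folds = folds, seed = seed, mode = mode,
                  C = C, gamma = gamma, ...)
    data.frame(R = R,
               mean_sensitivity = res$mean$sensitivity,
               mean_specificity = res$mean$specificity,
               mean_accuracy = res$mean$accuracy,
               sd_accuracy = res$sd$accuracy,
               gap = abs(res$mean$sensitivity - res$mean$specificity),
               valid = TRUE)
  })
  do.call(rbind, rows)
}

#' Select the factor count from a sweep table
#'
#' Codifies the selection protocol as a lexicographic rule: first keep
#' rows whose sensitivity-specificity gap is below `max_gap` (a balanced
#' operating point), then take the highest mean accuracy, breaking ties
#' by the lowest accuracy SD (stability) and finally by the smallest R
#' (cheapest model). If no row passes the gap filter the minimal-gap row
#' is returned with a warning.
#'
#' @param rows Sweep data.frame from [sweep_R()] (invalid rows ignored).
#' @param max_gap Maximum tolerated |sensitivity - specificity|
#'   (default 0.05).
#' @return The selected R value.
#' @export
select_R <- function(rows, max_gap = 0.05) {
  stopifnot(nrow(rows) > 0)
  if ("valid" %in% names(rows)) rows <- rows[rows$valid %in% TRUE, ]
  ok <- rows[rows$gap < max_gap, , drop = FALSE]
  if (nrow(ok) == 0L) {
    warning("no sweep row has gap < ", max_gap,
            "; returning the minimal-gap row")
    ok <- rows[which.min(rows$gap), , drop = FALSE]
  }
  ord <- order(-ok$mean_accuracy, ok$sd_accuracy, ok$R)
  ok$R[ord[1L]]
}
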