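#' Squared-Frobenius factorization objective
#'
#' The cost driving the factorization: `|| PD - PR %*% t(DR) ||_F^2`,
#' the squared Frobenius norm of the reconstruction residual.
#'
#' @param PD N x M nonnegative matrix (dense or sparse).
#' @param PR N x R nonnegative patient-loading matrix.
#' @param DR M x R nonnegative disease-loading matrix.
#' @return A single nonnegative number.
#' @export
nmf_objective <- function(PD, PR, DR) {
  if (nrow(PR) != nrow(PD) || nrow(DR) != ncol(PD) ||
      ncol(PR) != ncol(DR)) {
    stop("shape mismatch: PD is ", nrow(PD), "x", ncol(PD),
         ", PR is ", nrow(PR), "x", ncol(PR),
         ", DR is ", nrow(DR), "x", ncol(DR))
  }
  resid <- as.matrix(PD) - PR %*% t(DR)
  sum(resid^2)
}

#' Factorize a patient-disease matrix into latent risk factors
#'
#' Decomposes the binary patient-disease matrix `PD` (N patients x M
#' codes) into nonnegative factors `PD ~ PR %*% t(DR)`, where the R
#' columns are latent risk factors: `DR[m, r]` is how strongly code m
#' participates in factor r, and row n of `PR` is patient n's loading
#' vector, the feature vector used downstream by the risk classifier.
#'
#' Fitting alternates the Lee-Seung multiplicative updates for the
#' squared-Frobenius cost,
#' \deqn{PR \leftarrow PR \circ (PD\,DR) \oslash (PR\,(DR^T DR) + \epsilon)}
#' \deqn{DR \leftarrow DR \circ (PD^T PR) \oslash (DR\,(PR^T PR) + \epsilon)}
#' which keep both factors nonnegative and never increase the objective.
#' Iteration stops when the relative objective change drops below `tol`
#' or after `max_iter` updates. Factors are initialized from
#' Uniform(0, 1) draws under `seed`; with `n_restarts > 1` the fit is
#' repeated from consecutive derived seeds and the lowest-objective model
#' kept. The returned factors follow the usual identifiability
#' convention: columns of `DR` have unit Euclidean norm with the scale
#' absorbed into `PR`, leaving the reconstruction unchanged but giving
#' patient loadings a data-driven scale.
#'
#' @param PD Nonnegative N x M matrix (dense, sparse `Matrix`, or a
#'   `pd_matrix`).
#' @param R Number of latent factors; must satisfy `0 < R < M`.
#' @param seed Integer RNG seed for initialization.
#' @param max_iter Maximum update iterations (default 500).
#' @param tol Relative objective-change convergence threshold (default
#'   1e-4); `tol = 0` always runs `max_iter` iterations.
#' @param eps Denominator stabilizer (default 1e-12).
#' @param n_restarts Number of seeded restarts; best objective wins.
#' @param init Optional list with `PR` and `DR` start matrices
#'   (overrides seeding; used for reproducibility checks).
#' @return An `nmf_model` list: `PR`, `DR`, `R`, `objective_trace`
#'   (objective after every iteration, element 1 being the initial
#'   objective), `n_iter`, `seed`, `vocab_ref` (column codes when `PD`
#'   is a `pd_matrix`).
#' @examples
#' PD <- diag(2)
#' fit <- nmf_fit(PD, R = 2, seed = 1)
#' tail(fit$objective_trace, 1)  # ~0: exact rank-2 factorization exists
#' @export
nmf_fit <- function(PD, R, seed = 1L, max_iter = 500L, tol = 1e-4,
                    eps = 1e-12, n_restarts = 1L, init = NULL) {
  vocab_ref <- NULL
  if (inherits(PD, "pd_matrix")) {
    vocab_ref <- PD$col_codes
    PD <- PD$PD
  }
  if (min(PD) < 0) stop("PD must be nonnegative")
  N <- nrow(PD); M <- ncol(PD)
  if (R <= 0 || R >= M) {
    stop("R must satisfy 0 < R < M (R=", R, ", M=", M, ")")
  }
  best <- NULL
  for (restart in seq_len(n_restarts)) {
    s <- seed + restart - 1L
    fit <- nmf_fit_once(PD, R, s, max_iter, tol, eps, init)
    if (is.null(best) ||
        tail(fit$objective_trace, 1) < tail(best$objective_trace, 1)) {
      best <- fit
    }
  }
  best$vocab_ref <- vocab_ref
  best
}

nmf_fit_once <- function(PD, R, seed, max_iter, tol, eps, init = NULL) {
  N <- nrow(PD); M <- ncol(PD)
  if (is.null(init)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(seed)
    PR <- matrix(stats::runif(N * R), N, R)
    DR <- matrix(stats::runif(M * R), M, R)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  } else {
    PR <- as.matrix(init$PR)
    DR <- as.matrix(init$DR)
    stopifnot(nrow(PR) == N, nrow(DR) == M,
              ncol(PR) == R, ncol(DR) == R)
  }
  PDd <- PD          # keep sparse if sparse; products stay efficient
  PDt <- Matrix::t(PDd)
  obj <- nmf_objective(PD, PR, DR)
  trace <- numeric(max_iter + 1L)
  trace[1L] <- obj
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    PR <- PR * as.matrix(PDd %*% DR) / (PR %*% crossprod(DR) + eps)
    DR <- DR * as.matrix(PDt %*% PR) / (DR %*% crossprod(PR) + eps)
    if (!all(is.finite(PR)) || !all(is.finite(DR))) {
      stop("non-finite values at iteration ", it)
    }
    new_obj <- nmf_objective(PD, PR, DR)
    n_iter <- it
    trace[it + 1L] <- new_obj
    rel <- if (obj > 0) abs(obj - new_obj) / obj else 0
    obj <- new_obj
    if (tol > 0 && rel < tol) break
  }
  # identifiability convention: unit-L2 disease-loading columns, scale
  # absorbed into PR (reconstruction PR %*% t(DR) is unchanged)
  nrm <- sqrt(colSums(DR^2))
  nz <- nrm > 0
  DR[, nz] <- sweep(DR[, nz, drop = FALSE], 2, nrm[nz], "/")
  PR[, nz] <- sweep(PR[, nz, drop = FALSE], 2, nrm[nz], "*")
  structure(list(PR = PR, DR = DR, R = R,
                 objective_trace = trace[seq_len(n_iter + 1L)],
                 n_iter = n_iter, seed = seed, vocab_ref = NULL),
            class = "nmf_model")
}

#' @export
print.nmf_model <- function(x, ...) {
  cat("NMF model: ", nrow(x$PR), " patients x ", nrow(x$DR), " codes, R = ",
      x$R, "; ", x$n_iter, " iterations, objective ",
      format(tail(x$objective_trace, 1), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Fold unseen patients into a fitted factor space
#'
#' Projects binary code-presence rows into the latent factor space of a
#' fitted model with the disease loadings `DR` held fixed, by iterating
#' the patient-side multiplicative update on the new rows only. This is
#' the inductive path: test patients get loading vectors without
#' refitting, so no information flows from test to training data.
#' An all-zero input row maps to the all-zero loading (it is a fixed
#' point of the update).
#'
#' @param rows Binary matrix (n x M) or single length-M vector, indexed
#'   by the model's vocabulary.
#' @param DR The fitted M x R disease-loading matrix (or an `nmf_model`).
#' @param max_iter,tol,eps As in [nmf_fit()].
#' @param seed Seed for the nonnegative initialization of the loadings.
#' @return n x R nonnegative loading matrix.
#' @export
fold_in <- function(rows, DR, max_iter = 500L, tol = 1e-6, eps = 1e-12,
                    seed = 1L) {
  if (inherits(DR, "nmf_model")) DR <- DR$DR
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1L)
  if (ncol(rows) != nrow(DR)) {
    stop("row length ", ncol(rows), " does not match vocabulary size ",
         nrow(DR))
  }
  n <- nrow(rows); R <- ncol(DR)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  H <- matrix(stats::runif(n * R), n, R)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  DtD <- crossprod(DR)
  XD <- as.matrix(rows %*% DR)
  obj_row <- function(H) rowSums((as.matrix(rows) - H %*% t(DR))^2)
  obj <- sum(obj_row(H))
  for (it in seq_len(max_iter)) {
    H <- H * XD / (H %*% DtD + eps)
    new_obj <- sum(obj_row(H))
    rel <- if (obj > 0) abs(obj - new_obj) / obj else 0
    obj <- new_obj
    if (tol > 0 && rel < tol) break
  }
  # zero rows: the multiplicative update leaves H*0 numerator => decays
  # to ~0; make it exact
  zero <- Matrix::rowSums(rows) == 0
  H[zero, ] <- 0
  H
}

#' Persist / load a factor model
#'
#' The model is stored as plain-text files under a prefix: factors as
#' MatrixMarket (`.pr.mtx`, `.dr.mtx`), the vocabulary as one code per
#' line, the objective trace as CSV, and scalar metadata as YAML.
#'
#' @param model An `nmf_model`.
#' @param prefix Path prefix.
#' @export
persist_factor_model <- function(model, prefix) {
  Matrix::writeMM(methods::as(Matrix::Matrix(model$PR, sparse = TRUE),
                              "generalMatrix"), paste0(prefix, ".pr.mtx"))
  Matrix::writeMM(methods::as(Matrix::Matrix(model$DR, sparse = TRUE),
                              "generalMatrix"), paste0(prefix, ".dr.mtx"))
  if (!is.null(model$vocab_ref)) {
    writeLines(model$vocab_ref, paste0(prefix, ".vocab.txt"))
  }
  utils::write.csv(
    data.frame(iteration = seq_along(model$objective_trace) - 1L,
               objective = model$objective_trace),
    paste0(prefix, ".trace.csv"), row.names = FALSE)
  yaml::write_yaml(list(R = model$R, seed = model$seed,
                        n_iter = model$n_iter),
                   paste0(prefix, ".meta.yaml"))
  invisible(prefix)
}

#' @rdname persist_factor_model
#' @export
load_factor_model <- function(prefix) {
  PR <- as.matrix(Matrix::readMM(paste0(prefix, ".pr.mtx")))
  DR <- as.matrix(Matrix::readMM(paste0(prefix, ".dr.mtx")))
  meta <- yaml::read_yaml(paste0(prefix, ".meta.yaml"))
  tr <- utils::read.csv(paste0(prefix, ".trace.csv"))
  vocab_file <- paste0(prefix, ".vocab.txt")
  vocab <- if (file.exists(vocab_file)) readLines(vocab_file) else NULL
  structure(list(PR = PR, DR = DR, R = meta$R,
                 objective_trace = tr$objective, n_iter = meta$n_iter,
                 seed = meta$seed, vocab_ref = vocab),
            class = "nmf_model")
}
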