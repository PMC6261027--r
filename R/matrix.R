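#' Build the diagnosis-code vocabulary
#'
#' Returns the lexicographically sorted distinct codes appearing in at
#' least one history, minus any excluded codes. The target disease code
#' is always excluded: case histories cannot contain it after censoring,
#' and excluding it structurally keeps the feature space free of the
#' label.
#'
#' @param histories List of `patient_history` objects.
#' @param exclude Character vector of codes to drop (the cohort's target
#'   code is always added to this set when `target_code` is given).
#' @param target_code Optional target code, always excluded.
#' @return Ordered character vector of codes.
#' @export
build_vocabulary <- function(histories, exclude = character(),
                             target_code = NULL) {
  if (length(histories) == 0L) {
    warning("no histories: empty vocabulary")
    return(character())
  }
  codes <- unique(unlist(lapply(histories, function(h) h$records$code5),
                         use.names = FALSE))
  codes <- setdiff(codes, c(exclude, target_code))
  sort(codes)
}

#' Build the binary patient-disease diagnosis matrix
#'
#' Entry (n, m) is 1 exactly when patient n carries at least one record
#' of code m in their (censored) history — a presence matrix, not a count
#' matrix. Codes outside the supplied vocabulary are ignored, so a matrix
#' for unseen patients can be built against a training vocabulary
#' (inductive use); rows keep the order of the input histories.
#'
#' @param histories List of `patient_history` objects.
#' @param vocab Ordered code vector fixing the columns (from
#'   [build_vocabulary()]).
#' @param drop_empty_cols Drop all-zero columns and shrink the vocabulary
#'   accordingly (training-time option; such columns carry no
#'   factorization signal).
#' @return A `pd_matrix` list: `PD` (sparse binary dgCMatrix), `row_ids`,
#'   `col_codes`, `labels` (per-row `"case"`/`"control"`).
#' @export
build_matrix <- function(histories, vocab, drop_empty_cols = FALSE) {
  n <- length(histories)
  m <- length(vocab)
  jj <- lapply(histories, function(h) {
    cols <- match(unique(h$records$code5), vocab)
    cols[!is.na(cols)]
  })
  ii <- rep.int(seq_len(n), lengths(jj))
  PD <- Matrix::sparseMatrix(i = ii, j = unlist(jj, use.names = FALSE),
                             x = 1, dims = c(n, m))
  row_ids <- vapply(histories, function(h) h$patient_id, character(1))
  labels <- vapply(histories, function(h) h$label, character(1))
  if (drop_empty_cols) {
    keep <- Matrix::colSums(PD) > 0
    PD <- PD[, keep, drop = FALSE]
    vocab <- vocab[keep]
  }
  pd_matrix(PD, row_ids, vocab, labels)
}

pd_matrix <- function(PD, row_ids, col_codes, labels) {
  stopifnot(nrow(PD) == length(row_ids), ncol(PD) == length(col_codes),
            length(labels) == length(row_ids),
            !anyDuplicated(row_ids), !anyDuplicated(col_codes))
  dimnames(PD) <- list(row_ids, col_codes)
  structure(list(PD = PD, row_ids = unname(row_ids),
                 col_codes = col_codes, labels = unname(labels)),
            class = "pd_matrix")
}

#' @export
print.pd_matrix <- function(x, ...) {
  cat("Patient-disease matrix:", nrow(x$PD), "patients x",
      ncol(x$PD), "codes;", length(x$PD@x), "nonzeros;",
      sum(x$labels == "case"), "cases\n")
  invisible(x)
}

#' Persist / load a patient-disease matrix
#'
#' The matrix is written as a MatrixMarket coordinate file (1-based, per
#' the format) with three plain-text sidecars: `<prefix>.rows.txt`
#' (patient IDs), `<prefix>.cols.txt` (codes) and `<prefix>.labels.txt`
#' (per-row arm). Loading verifies that sidecar lengths match the matrix
#' shape.
#'
#' @param pdm A `pd_matrix`.
#' @param prefix Path prefix; files `<prefix>.mtx` etc. are created.
#' @return `persist_matrix` returns the prefix invisibly; `load_matrix`
#'   returns the reconstructed `pd_matrix`.
#' @export
persist_matrix <- function(pdm, prefix) {
  Matrix::writeMM(methods::as(methods::as(pdm$PD, "dMatrix"), "generalMatrix"),
                  paste0(prefix, ".mtx"))
  writeLines(pdm$row_ids, paste0(prefix, ".rows.txt"))
  writeLines(pdm$col_codes, paste0(prefix, ".cols.txt"))
  writeLines(pdm$labels, paste0(prefix, ".labels.txt"))
  invisible(prefix)
}

#' @rdname persist_matrix
#' @export
load_matrix <- function(prefix) {
  PD <- Matrix::readMM(paste0(prefix, ".mtx"))
  # binary matrices round-trip through MatrixMarket pattern files
  PD <- methods::as(methods::as(PD, "dMatrix"), "CsparseMatrix")
  row_ids <- readLines(paste0(prefix, ".rows.txt"))
  col_codes <- readLines(paste0(prefix, ".cols.txt"))
  labels <- readLines(paste0(prefix, ".labels.txt"))
  if (length(row_ids) != nrow(PD) || length(col_codes) != ncol(PD) ||
      length(labels) != nrow(PD)) {
    stop("sidecar/matrix shape mismatch for prefix ", prefix)
  }
  pd_matrix(PD, row_ids, col_codes, labels)
}
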