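# Shared fixture builders.

# Write a records CSV from a data.frame of (patient_id, visit_date, code)
# and read it back through the package reader.
write_records_csv <- function(df, path = tempfile(fileext = ".csv")) {
  writeLines(c("patient_id,visit_date,icd9_code",
               sprintf("%s,%s,%s", df$patient_id, df$visit_date, df$code)),
             path)
  path
}

# A valid 10-character alphanumeric patient id.
pid <- function(i) sprintf("PAT%07d", i)

# Minimal patient_history constructor for matrix-level tests.
make_history <- function(patient_id, label, codes,
                         dates = rep("2003-06-01", length(codes))) {
  recs <- data.frame(
    patient_id = rep(patient_id, length(codes)),
    visit_date_raw = dates,
    code_raw = codes,
    stringsAsFactors = FALSE
  )
  recs$visit_date <- as.Date(dates)
  recs$code5 <- codes
  structure(list(patient_id = patient_id, label = label, records = recs,
                 censor_date = NULL),
            class = "patient_history")
}

# Build a labelled pd_matrix directly from a planted binary matrix.
pdm_from_planted <- function(pf) {
  PD <- Matrix::Matrix(pf$PD, sparse = TRUE)
  n <- nrow(PD)
  structure(list(PD = PD, row_ids = sprintf("SYN%07d", seq_len(n)),
                 col_codes = pf$codes, labels = pf$truth$labels),
            class = "pd_matrix")
}
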