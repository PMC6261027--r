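#' Read raw diagnostic records
#'
#' Reads a delimited text file of outpatient diagnostic records, one
#' patient-visit-diagnosis event per row. The expected dialect is
#' comma-separated UTF-8 with columns \code{patient_id,visit_date,icd9_code}
#' (header optional), dates in ISO-8601. Raw field values are preserved;
#' normalization and noise filtering happen in [filter_noise()].
#'
#' Rows with the wrong number of columns are skipped with a warning; they
#' do not abort the read.
#'
#' @param path Path to the records file.
#' @param sep Field separator (default comma).
#' @param header Logical; whether the first row is a header. If `NA`
#'   (default), a header is detected by checking whether the first row's
#'   second field parses as a date.
#' @return A data.frame of class `diag_records` with character columns
#'   `patient_id`, `visit_date_raw`, `code_raw`, plus a `visit_date` Date
#'   column (`NA` where unparseable) and a `code5` column (all `NA` until
#'   normalization). The number of skipped rows is available as
#'   `attr(x, "n_skipped")`.
#' @seealso [filter_noise()], [normalize_icd9()]
#' @export
read_diagnostic_records <- function(path, sep = ",", header = NA) {
  if (!file.exists(path)) stop("cannot read records file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(empty_diag_records())
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (is.na(header)) {
    first <- fields[[1L]]
    header <- length(first) >= 2L && is.na(parse_iso_date(first[2L]))
  }
  if (isTRUE(header)) {
    fields <- fields[-1L]
    if (length(fields) == 0L) return(empty_diag_records())
  }
  nf <- lengths(fields)
  bad <- nf != 3L
  if (any(bad)) {
    warning(sum(bad), " row(s) with wrong column count skipped")
    fields <- fields[!bad]
  }
  if (length(fields) == 0L) {
    out <- empty_diag_records()
    attr(out, "n_skipped") <- sum(bad)
    return(out)
  }
  m <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
  out <- data.frame(
    patient_id = m[, 1L],
    visit_date_raw = m[, 2L],
    code_raw = m[, 3L],
    stringsAsFactors = FALSE
  )
  out$visit_date <- parse_iso_date(out$visit_date_raw)
  out$code5 <- NA_character_
  class(out) <- c("diag_records", "data.frame")
  attr(out, "n_skipped") <- sum(bad)
  out
}

empty_diag_records <- function() {
  out <- data.frame(
    patient_id = character(), visit_date_raw = character(),
    code_raw = character(), stringsAsFactors = FALSE
  )
  out$visit_date <- as.Date(character())
  out$code5 <- character()
  class(out) <- c("diag_records", "data.frame")
  attr(out, "n_skipped") <- 0L
  out
}

#' Write diagnostic records
#'
#' Writes records in the same CSV dialect [read_diagnostic_records()] reads,
#' using the normalized code where available so that read-write-read
#' round-trips are stable.
#'
#' @param records A `diag_records` data.frame.
#' @param path Output file path.
#' @export
write_diagnostic_records <- function(records, path) {
  code <- ifelse(is.na(records$code5), records$code_raw, records$code5)
  df <- data.frame(
    patient_id = records$patient_id,
    visit_date = format(records$visit_date, "%Y-%m-%d"),
    icd9_code = code,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Strict ISO-8601 parse: returns NA instead of warning on garbage.
parse_iso_date <- function(x) {
  ok <- grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)
  out <- rep(as.Date(NA), length(x))
  if (any(ok)) out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

#' Normalize an ICD-9-CM code to the five-character form
#'
#' Claims files write the same diagnosis in several surface forms
#' (\code{"714.0"}, \code{"7140"}, \code{"71400"}). This maps each to a
#' canonical five-character code: the decimal point is removed, the
#' integer part (category) is left-padded with zeros to three characters,
#' and the fractional part (subclassification) is right-padded with zeros
#' to two characters; \code{"714.0"} becomes \code{"71400"}. Supplementary
#' V codes keep the letter plus a two-digit category and two-digit
#' fraction; external-cause E codes carry a four-digit numeric body
#' (three-digit category plus one subclassification digit). The function
#' is idempotent and vectorized.
#'
#' @param code_raw Character vector of raw codes.
#' @return Character vector of five-character codes matching
#'   `[0-9]{5}`, `V[0-9]{4}` or `E[0-9]{4}`; `NA` where the input cannot
#'   be normalized (illegal characters, empty, category overflow).
#' @examples
#' normalize_icd9("714.0")  # "71400"
#' normalize_icd9("7.1")    # "00710"
#' normalize_icd9(c("V04.5", "E810.1"))
#' @export
normalize_icd9 <- function(code_raw) {
  vapply(code_raw, normalize_icd9_one, character(1), USE.NAMES = FALSE)
}

normalize_icd9_one <- function(code) {
  if (is.na(code)) return(NA_character_)
  code <- toupper(trimws(code))
  if (!nzchar(code)) return(NA_character_)
  if (!grepl("^[0-9VE.]+$", code)) return(NA_character_)
  if (lengths(regmatches(code, gregexpr(".", code, fixed = TRUE))) > 1L) {
    return(NA_character_)
  }
  letter <- ""
  body <- code
  if (grepl("^[VE]", code)) {
    letter <- substr(code, 1L, 1L)
    body <- substring(code, 2L)
    if (!nzchar(body) || grepl("[VE]", body)) return(NA_character_)
  }
  # category width: digits before the (implied) decimal point
  int_w <- switch(letter, "V" = 2L, "E" = 3L, 3L)
  frac_w <- if (letter == "E") 1L else 2L
  if (grepl(".", body, fixed = TRUE)) {
    parts <- strsplit(body, ".", fixed = TRUE)[[1L]]
    int_part <- parts[1L]
    frac_part <- if (length(parts) >= 2L) parts[2L] else ""
  } else {
    # undotted: leading digits up to the category width, remainder is
    # the subclassification
    int_part <- substr(body, 1L, min(nchar(body), int_w))
    frac_part <- if (nchar(body) > int_w) substring(body, int_w + 1L) else ""
  }
  if (nchar(int_part) > int_w || nchar(frac_part) > frac_w) {
    return(NA_character_)
  }
  int_part <- paste0(strrep("0", int_w - nchar(int_part)), int_part)
  frac_part <- paste0(frac_part, strrep("0", frac_w - nchar(frac_part)))
  if (!nzchar(gsub("0", "", paste0(int_part, frac_part))) && letter == "") {
    # all-zero numeric code is not a valid ICD-9 category
    return(NA_character_)
  }
  paste0(letter, int_part, frac_part)
}

#' Default noise-filtering rules
#'
#' @param window Length-2 Date (or ISO string) vector giving the plausible
#'   visit-date window, inclusive.
#' @param id_length Required patient-identifier length (claims IDs have a
#'   fixed width; 10 by default).
#' @param id_pattern Regular expression a valid patient identifier must
#'   match in full (alphanumeric by default).
#' @return A list of rule parameters for [filter_noise()].
#' @export
noise_rules <- function(window = c("2000-01-01", "2008-12-31"),
                        id_length = 10L,
                        id_pattern = "^[A-Za-z0-9]+$") {
  list(window = as.Date(window), id_length = as.integer(id_length),
       id_pattern = id_pattern)
}

#' Remove noise records and normalize surviving codes
#'
#' Three noise types are removed from claims records before any analysis:
#' \describe{
#'   \item{rule 1 (incorrect format)}{diagnosis codes that cannot be
#'     normalized to the five-character form, and patient identifiers
#'     failing the configured length/charset check;}
#'   \item{rule 2 (missing/implausible)}{missing or incomplete fields, and
#'     visit dates that do not parse or fall outside the plausible window;}
#'   \item{rule 3 (garbled)}{fields containing non-printable characters or
#'     that are empty after whitespace stripping.}
#' }
#' Each removed record is attributed to exactly one rule (checked in the
#' order 3, 2, 1). Surviving records are unchanged except that `code5`
#' is filled with the normalized code.
#'
#' @param records A `diag_records` data.frame from
#'   [read_diagnostic_records()].
#' @param rules Rule parameters from [noise_rules()].
#' @return A list with `records` (clean, normalized) and `report`, a
#'   `noise_report` list with `n_input`, `n_removed` and
#'   `removals_by_rule`.
#' @export
filter_noise <- function(records, rules = noise_rules()) {
  n_input <- nrow(records)
  code5 <- normalize_icd9(records$code_raw)

  garbled_field <- function(x) {
    is.na(x) | !nzchar(trimws(x)) | grepl("[[:cntrl:]]", x)
  }
  rule3 <- garbled_field(records$patient_id) |
    garbled_field(records$visit_date_raw) |
    garbled_field(records$code_raw)

  in_window <- !is.na(records$visit_date) &
    records$visit_date >= rules$window[1L] &
    records$visit_date <= rules$window[2L]
  rule2 <- !rule3 & !in_window

  id_ok <- nchar(records$patient_id) == rules$id_length &
    grepl(rules$id_pattern, records$patient_id)
  rule1 <- !rule3 & !rule2 & (is.na(code5) | !id_ok)

  keep <- !(rule1 | rule2 | rule3)
  clean <- records[keep, , drop = FALSE]
  clean$code5 <- code5[keep]
  rownames(clean) <- NULL
  class(clean) <- c("diag_records", "data.frame")

  report <- structure(list(
    n_input = n_input,
    n_removed = sum(!keep),
    removals_by_rule = list(
      incorrect_format = sum(rule1),
      missing_or_implausible = sum(rule2),
      garbled = sum(rule3)
    )
  ), class = "noise_report")
  list(records = clean, report = report)
}

#' @export
print.noise_report <- function(x, ...) {
  cat("Noise report:", x$n_input, "records read,", x$n_removed, "removed\n")
  for (nm in names(x$removals_by_rule)) {
    cat(sprintf("  %-24s %d\n", nm, x$removals_by_rule[[nm]]))
  }
  invisible(x)
}

#' Serialize a noise report as YAML
#'
#' @param report A `noise_report` from [filter_noise()].
#' @param path Output file path.
#' @export
write_noise_report <- function(report, path) {
  yaml::write_yaml(unclass(report), path)
  invisible(path)
}
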