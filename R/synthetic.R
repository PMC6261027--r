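#' Configuration for the synthetic EMR generator
#'
#' Collects the knobs of the planted-factor cohort simulator. The
#' defaults describe a desk-scale cohort with clear latent structure:
#' 500 cases and 500 controls (a balanced analysis sample drawn from a
#' notionally rare disease), 400 diagnosis codes, five latent disease
#' themes of which two are case-enriched with a three-fold loading boost,
#' visit streams spanning a nine-year window, and a small fraction of
#' injected malformed records so the noise filter has work to do.
#'
#' @param n_cases,n_controls Arm sizes.
#' @param vocab_size Number of distinct (non-target) diagnosis codes M.
#' @param k_themes Number of latent disease themes.
#' @param theme_code_sparsity Proportion of codes active in each theme.
#' @param case_theme_boost Multiplier applied to case patients' weights
#'   on the risk theme(s) (>= 1; 1 = null model, cases exchangeable with
#'   controls).
#' @param n_risk_themes How many themes are case-enriched.
#' @param visits_per_year_mean Mean visits per patient-year (Poisson).
#' @param years Window length in years.
#' @param noise_rate Proportion of additional malformed records injected.
#' @param registry_false_rate Proportion of non-case IDs added to the
#'   registry file (the registry conjunct must reject these).
#' @param target_code The target-disease code (default `"71400"`).
#' @param intensity Overall scale of the patient weights; tunes expected
#'   codes per patient.
#' @param seed Integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_cases = 500L, n_controls = 500L,
                         vocab_size = 400L, k_themes = 5L,
                         theme_code_sparsity = 0.1,
                         case_theme_boost = 3, n_risk_themes = 2L,
                         visits_per_year_mean = 4, years = 9L,
                         noise_rate = 0.01, registry_false_rate = 0,
                         target_code = "71400", intensity = 0.15,
                         seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              vocab_size = as.integer(vocab_size),
              k_themes = as.integer(k_themes),
              theme_code_sparsity = theme_code_sparsity,
              case_theme_boost = case_theme_boost,
              n_risk_themes = as.integer(n_risk_themes),
              visits_per_year_mean = visits_per_year_mean,
              years = as.integer(years),
              noise_rate = noise_rate,
              registry_false_rate = registry_false_rate,
              target_code = target_code,
              intensity = intensity,
              seed = as.integer(seed))
  stopifnot(cfg$n_cases > 0, cfg$n_controls > 0, cfg$vocab_size > 0,
            cfg$k_themes > 0, cfg$k_themes < cfg$vocab_size,
            cfg$theme_code_sparsity > 0, cfg$theme_code_sparsity <= 1,
            cfg$case_theme_boost >= 1,
            cfg$n_risk_themes >= 1, cfg$n_risk_themes <= cfg$k_themes,
            cfg$noise_rate >= 0, cfg$noise_rate <= 1)
  class(cfg) <- "synth_config"
  cfg
}

#' Draw a binary patient-disease matrix with planted factor structure
#'
#' Builds ground-truth nonnegative factors and emits a binary matrix
#' from them. Each theme activates about `theme_code_sparsity * M` codes
#' with Uniform(0.5, 1.5) loadings (`true_DR`); each patient draws
#' Gamma(4, 4)-distributed theme weights scaled by `intensity`
#' (`true_PR`), and case patients' weights on the risk theme(s) are
#' multiplied by `case_theme_boost`. Entries are then
#' `Bernoulli(1 - exp(-(true_PR %*% t(true_DR))[n, m]))` — a
#' presence/absence observation of an underlying diagnosis intensity, so
#' the binary matrix keeps approximate low-rank structure. With
#' `bernoulli = FALSE` the continuous intensity matrix itself is
#' returned (an exactly rank-k nonnegative product, useful for
#' exact-recovery checks).
#'
#' @param config A `synth_config`.
#' @param bernoulli Apply the Bernoulli observation step (default TRUE).
#' @return List with `PD` (N x M matrix, cases first), `truth` (a
#'   `synth_truth`: `true_PR`, `true_DR`, `risk_theme_index`, `labels`)
#'   and `codes` (the M code strings).
#' @export
planted_factor_matrix <- function(config, bernoulli = TRUE) {
  cfg <- config
  set.seed(cfg$seed)
  N <- cfg$n_cases + cfg$n_controls
  M <- cfg$vocab_size
  k <- cfg$k_themes
  codes_per_theme <- max(1L, round(cfg$theme_code_sparsity * M))

  codes <- synth_code_pool(M, exclude = cfg$target_code)

  true_DR <- matrix(0, M, k)
  for (r in seq_len(k)) {
    active <- sample.int(M, codes_per_theme)
    true_DR[active, r] <- stats::runif(codes_per_theme, 0.5, 1.5)
  }
  if (any(colSums(true_DR) == 0)) stop("degenerate config: empty theme")

  labels <- c(rep("case", cfg$n_cases), rep("control", cfg$n_controls))
  true_PR <- matrix(stats::rgamma(N * k, shape = 4, rate = 4), N, k) *
    cfg$intensity
  risk_idx <- seq_len(cfg$n_risk_themes)
  true_PR[labels == "case", risk_idx] <-
    true_PR[labels == "case", risk_idx] * cfg$case_theme_boost

  lambda <- true_PR %*% t(true_DR)
  PD <- if (bernoulli) {
    matrix(stats::rbinom(N * M, 1L, 1 - exp(-lambda)), N, M)
  } else {
    lambda
  }
  truth <- structure(list(true_PR = true_PR, true_DR = true_DR,
                          risk_theme_index = risk_idx, labels = labels),
                     class = "synth_truth")
  list(PD = PD, truth = truth, codes = codes)
}

# Deterministic pool of distinct valid five-digit codes, target excluded.
synth_code_pool <- function(M, exclude = "71400") {
  pool <- sprintf("%03d%02d", rep(1:999, each = 10), rep(seq(0, 90, 10), 999))
  pool <- setdiff(pool, exclude)
  if (M > length(pool)) stop("vocab_size too large for the code pool")
  pool[seq_len(M)]
}

#' Generate a synthetic longitudinal EMR cohort
#'
#' Expands the planted binary matrix of [planted_factor_matrix()] into
#' dated visit records over the observation window. Every active code of
#' a patient yields at least one record; additional records (visit
#' counts ~ Poisson(`visits_per_year_mean * years`)) re-sample the
#' patient's active codes, so duplicate diagnoses occur as in real
#' claims. Case patients receive two target-code records dated after all
#' their non-target records, so censoring at the first target diagnosis
#' reproduces exactly the planted history, and their IDs are written to
#' the registry. A `noise_rate` fraction of malformed records (bad ID
#' lengths, garbled codes, out-of-window dates) is appended and shuffled
#' in. About half of all clean codes are written in dotted raw form
#' (`"714.0"`-style) to exercise normalization.
#'
#' @param config A `synth_config`.
#' @param dir Output directory (created if missing).
#' @return List of written paths: `records` (CSV), `registry` (one ID
#'   per line), `truth_prefix` (MatrixMarket factors + labels), plus the
#'   in-memory `truth` and `codes`.
#' @export
generate_synthetic_emr <- function(config, dir) {
  cfg <- config
  planted <- planted_factor_matrix(cfg)  # seeds the RNG stream
  PD <- planted$PD; codes <- planted$codes; truth <- planted$truth
  N <- nrow(PD)
  labels <- truth$labels

  window_start <- as.Date("2000-01-01")
  window_days <- cfg$years * 365L
  # non-target records live in the first 80% of the window; case target
  # diagnoses in the last 20%, so censoring keeps every planted record
  pre_days <- floor(window_days * 0.8)

  ids <- sprintf("P%09d", seq_len(N))
  rows <- vector("list", N)
  for (n in seq_len(N)) {
    active <- codes[PD[n, ] == 1L]
    n_extra <- stats::rpois(1L, cfg$visits_per_year_mean * cfg$years)
    code_stream <- c(active,
                     if (length(active) > 0 && n_extra > 0)
                       sample(active, n_extra, replace = TRUE))
    if (length(code_stream) == 0L) {
      # ensure every patient has >= 1 in-window record
      code_stream <- sample(codes, 1L)
    }
    dates <- window_start +
      sample.int(pre_days, length(code_stream), replace = TRUE) - 1L
    if (labels[n] == "case") {
      tgt_dates <- window_start + pre_days +
        sort(sample.int(window_days - pre_days - 1L, 2L)) - 1L
      code_stream <- c(code_stream, rep(cfg$target_code, 2L))
      dates <- c(dates, tgt_dates)
    }
    rows[[n]] <- data.frame(patient_id = ids[n],
                            visit_date = format(dates, "%Y-%m-%d"),
                            icd9_code = code_stream,
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)

  # dotted raw form for roughly half of the numeric codes
  dot <- stats::runif(nrow(df)) < 0.5 & grepl("^[0-9]{5}$", df$icd9_code)
  df$icd9_code[dot] <- paste0(substr(df$icd9_code[dot], 1, 3), ".",
                              substr(df$icd9_code[dot], 4, 5))

  n_noise <- round(cfg$noise_rate * nrow(df))
  if (n_noise > 0L) {
    kinds <- rep_len(c("bad_id", "garbled_code", "bad_date"), n_noise)
    noise <- data.frame(
      patient_id = ifelse(kinds == "bad_id", "SHORT", ids[1L]),
      visit_date = ifelse(kinds == "bad_date", "1899-01-01",
                          format(window_start + 10L, "%Y-%m-%d")),
      icd9_code = ifelse(kinds == "garbled_code", "##!!", codes[1L]),
      stringsAsFactors = FALSE
    )
    df <- rbind(df, noise)
  }
  df <- df[sample.int(nrow(df)), , drop = FALSE]

  registry <- ids[labels == "case"]
  n_false <- round(cfg$registry_false_rate * length(registry))
  if (n_false > 0L) {
    registry <- c(registry,
                  sample(ids[labels == "control"], n_false))
  }

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records_path <- file.path(dir, "records.csv")
  utils::write.csv(df, records_path, row.names = FALSE, quote = FALSE)
  registry_path <- file.path(dir, "registry.txt")
  writeLines(registry, registry_path)

  truth_prefix <- file.path(dir, "truth")
  Matrix::writeMM(methods::as(Matrix::Matrix(truth$true_PR, sparse = TRUE),
                              "generalMatrix"),
                  paste0(truth_prefix, ".pr.mtx"))
  Matrix::writeMM(methods::as(Matrix::Matrix(truth$true_DR, sparse = TRUE),
                              "generalMatrix"),
                  paste0(truth_prefix, ".dr.mtx"))
  writeLines(labels, paste0(truth_prefix, ".labels.txt"))
  writeLines(ids, paste0(truth_prefix, ".ids.txt"))
  writeLines(codes, paste0(truth_prefix, ".codes.txt"))

  list(records = records_path, registry = registry_path,
       truth_prefix = truth_prefix, truth = truth, codes = codes,
       patient_ids = ids)
}

#' Greedy factor-matching cosine similarity
#'
#' Matches fitted factor columns to ground-truth columns greedily by
#' cosine similarity (best available pair first, without replacement)
#' and returns the per-pair similarities — a subspace-recovery
#' diagnostic for the factorization on synthetic data.
#'
#' @param fitted,truth Matrices with the same row count (columns =
#'   factors).
#' @return Numeric vector of matched cosine similarities, one per truth
#'   column (length `min(ncol(fitted), ncol(truth))`).
#' @export
match_factors_cosine <- function(fitted, truth) {
  norm_cols <- function(A) {
    nrm <- sqrt(colSums(A^2))
    nrm[nrm == 0] <- 1
    sweep(A, 2, nrm, "/")
  }
  S <- crossprod(norm_cols(as.matrix(fitted)), norm_cols(as.matrix(truth)))
  k <- min(ncol(fitted), ncol(truth))
  out <- numeric(k)
  for (i in seq_len(k)) {
    best <- arrayInd(which.max(S), dim(S))
    out[i] <- S[best[1L], best[2L]]
    S[best[1L], ] <- -Inf
    S[, best[2L]] <- -Inf
  }
  out
}
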