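# emrisk

Early disease risk assessment from longitudinal outpatient diagnosis
records.

Chronic diseases such as rheumatoid arthritis (RA, ICD-9-CM 714.0) leave
traces in a patient's claims history — recurring symptoms and comorbid
conditions — years before the formal diagnosis. `emrisk` assesses
individual risk from the *pre-diagnosis* record alone. It is written for
epidemiologists and biostatisticians working with claims-style data
(one `patient_id, visit_date, icd9_code` row per diagnosis event) and
ships a synthetic EMR generator with planted latent structure so the
full pipeline is testable without access-restricted cohorts.

## The method

1. **Preprocess** — normalize ICD-9-CM codes to the five-character form
   (714.0 → 71400) and remove three noise types: malformed
   codes/identifiers, missing or out-of-window dates, garbled content.
2. **Cohort** — cases need ≥ 2 target-code diagnoses *and* membership in
   a catastrophic-illness registry; each case history is censored
   strictly before the first target diagnosis. Controls carry no
   target-code evidence at all.
3. **Matrix** — the binary patient–disease matrix
   `PD ∈ {0,1}^(N×M)`, `PD[n,m] = 1` iff patient *n* ever carries code
   *m* in the censored history.
4. **Latent risk factors** — non-negative matrix factorization
   `PD ≈ PR · DRᵀ` (R factors, `R < M`) by Lee–Seung multiplicative
   updates on the squared Frobenius cost
   `‖PD − PR·DRᵀ‖²`; the rows of `PR` are the patients' risk-factor
   loadings. Unseen patients are folded in against a fixed `DR`.
5. **Assessment** — an RBF-kernel SVM (`C = 2`, `γ = 0.03125`,
   re-tunable by grid search) classifies loadings; evaluation is
   stratified 10-fold cross-validation reporting sensitivity `TP/CP`,
   specificity `TN/CN`, accuracy `(TP+TN)/(CP+CN)` with population-SD
   stability, plus an R-sweep and a lexicographic rank-selection rule
   (gap < 5 % → accuracy → SD → smallest R).

See `vignettes/risk-assessment-pipeline.Rmd` for the model, design
decisions and the generator's scope.

## Worked example

```r
library(emrisk)

cfg <- synth_config(n_cases = 60, n_controls = 60, vocab_size = 120,
                    k_themes = 4, seed = 7)
sim <- generate_synthetic_emr(cfg, tempfile("demo"))

fl  <- filter_noise(read_diagnostic_records(sim$records))
print(fl$report)
coh <- build_cohort(fl$records, read_registry(sim$registry), "71400")
print(coh)

hs    <- c(coh$cases, coh$controls)
vocab <- build_vocabulary(hs, target_code = "71400")
pdm   <- build_matrix(hs, vocab)
print(pdm)

fit <- nmf_fit(pdm, R = 4, seed = 1)
print(fit)
res <- run_cv(pdm, R = 4, folds = 10, seed = 1)
print(res)
```

```
Noise report: 5760 records read, 57 removed
  incorrect_format         38
  missing_or_implausible   19
  garbled                  0
Case-control cohort (target 71400 )
  cases:    60
  controls: 60
  window:   2000-01-01 to 2008-12-31
Patient-disease matrix: 120 patients x 41 codes; 1120 nonzeros; 60 cases
NMF model: 120 patients x 41 codes, R = 4; 122 iterations, objective 632.034
10-fold evaluation:
  sensitivity  0.6667 +/- 0.2357
  specificity  0.8667 +/- 0.1633
  accuracy     0.7667 +/- 0.1333
```

Reading the output: the generator injected ~1 % malformed records and
the filter removed exactly those (57 of 5760); all 60 planted cases were
recovered by the registry-confirmed, censored cohort selection; the
binary matrix keeps only codes observed in histories (41 of the 120
simulated codes are active under 4 themes); and the cross-validated
classifier recovers the planted case enrichment well above the 0.5
chance level — modestly here, since 120 patients is a small sample for
this signal. At the validation scale used by the acceptance script
(1,000 patients, 400 codes, 5 themes) mean sensitivity and specificity
both exceed 0.85.

A thin command-line front end over the same functions is at
`inst/cli/emrisk.R` (subcommands `preprocess`, `cohort`, `matrix`,
`fit`, `evaluate`, `sweep-r`, `simulate`).

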