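---
title: "Latent risk factors from diagnosis histories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent risk factors from diagnosis histories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emrisk)
```

## The problem

Chronic diseases such as rheumatoid arthritis (RA) leave traces in a
patient's outpatient record years before the formal diagnosis: recurring
symptoms, comorbid conditions, patterns of clinic visits. `emrisk` asks
whether a patient's *pre-diagnosis* history alone — a stream of dated
ICD-9-CM codes — predicts who will later be diagnosed, and answers it
with a three-stage model: a binary patient–disease matrix, non-negative
matrix factorization (NMF) into latent risk factors, and a kernel
classifier on the factor loadings.

The package is written for claims-style data: one row per
patient–visit–diagnosis event. Because the national claims cohorts this
kind of study draws on are access-restricted, the package ships a
synthetic generator with planted latent structure, so the whole pipeline
is testable and its statistical behaviour measurable end to end.

## The model

**Patient–disease matrix.** Given patients $P$ and diagnosis codes $D$,
the matrix $PD \in \{0,1\}^{N \times M}$ has $PD_{n,m} = 1$ exactly when
patient $n$ ever carries code $m$ in their censored history. Presence,
not count: repeated diagnoses of the same code do not increase the
entry. For cases, the history is censored strictly before the first
target-disease diagnosis, so the target code never appears in a case
row; we additionally exclude the target code from the vocabulary so it
is structurally absent from the feature space.

**Factorization.** $PD$ is approximated by nonnegative factors
$PD \approx PR \cdot DR^{\top}$ with $PR \in \mathbb{R}_{\ge 0}^{N
\times R}$, $DR \in \mathbb{R}_{\ge 0}^{M \times R}$ and $R < M$. The
$R$ columns are *latent risk factors*: groups of codes that co-occur
across patients. Fitting minimizes the squared Frobenius cost
$\lVert PD - PR\,DR^{\top} \rVert_F^2$ by the Lee–Seung multiplicative
updates

$$PR \leftarrow PR \circ \frac{PD\,DR}{PR\,(DR^{\top}DR) + \varepsilon},
\qquad
DR \leftarrow DR \circ \frac{PD^{\top}PR}{DR\,(PR^{\top}PR) + \varepsilon},$$

which preserve nonnegativity and never increase the cost — a guarantee
the test suite checks against an independently coded straight-line
implementation of the same updates on batches of random binary matrices.

**Classification.** Row $n$ of $PR$ is patient $n$'s feature vector. A
soft-margin SVM with RBF kernel ($C = 2$, $\gamma = 0.03125$, both
re-tunable by `grid_search()`) separates cases from controls in loading
space. Evaluation is stratified 10-fold cross-validation with
sensitivity $TP/CP$, specificity $TN/CN$, accuracy $(TP+TN)/(CP+CN)$,
macro-averaged over folds; fold-to-fold variation is summarized by the
population standard deviation (divide by $N$, not $N-1$).

## Design choices where the design was open

**Inductive vs transductive evaluation.** The historical protocol for
this pipeline factorizes each dataset once before cross-validation, so
the factor space has seen the (unlabeled) test rows. `run_cv()` defaults
to the stricter inductive protocol — NMF on the training folds only,
held-out rows projected by `fold_in()` with $DR$ fixed — and keeps the
transductive protocol behind `mode = "transductive"` for comparability.
Fold-in iterates the patient-side update only; since that subproblem is
a convex nonnegative least-squares in the row loading, refolded training
rows reconstruct essentially as well as they did during training (the
suite enforces a 1.05 ratio bound).

**Factor scale.** NMF is scale-indeterminate: $PR \Lambda \cdot
(DR \Lambda^{-1})^{\top}$ reconstructs identically for any positive
diagonal $\Lambda$. A fixed-width RBF kernel downstream makes the scale
matter, so `nmf_fit()` adopts the usual convention of unit-$L_2$ $DR$
columns with the scale absorbed into $PR$. This leaves the
reconstruction and objective trace untouched and gives loadings a
data-driven magnitude, so one kernel width behaves comparably across
refits (e.g. across CV folds).

**Case definition.** A case needs at least `min_dx = 2` target-code
diagnoses *and* membership in the catastrophic-illness registry; the
phrase "diagnosed more than twice" in the source literature is
ambiguous between $\ge 2$ and $\ge 3$, so the threshold is a parameter
rather than a constant. Patients with target-code evidence below the
threshold are excluded from both arms: they are neither confirmed cases
nor clean controls, and treating them as controls would contaminate the
labels.

**Rank selection.** The published guidance combines three criteria
loosely (highest accuracy, low SD, sensitivity–specificity distance
below 5%). `select_R()` codifies them lexicographically: filter to rows
with gap $< 0.05$, then maximize mean accuracy, break ties by lower
accuracy SD, then by smaller $R$; if nothing passes the gap filter the
minimal-gap row is returned with a warning.

**Noise rules.** Three removal rules — unnormalizable codes / malformed
patient IDs, missing or out-of-window dates, garbled content — are
config-driven (`noise_rules()`): the exact sub-rules used on the
original restricted cohort are not recoverable, so window, ID length
and charset are parameters with documented defaults (2000-01-01 to
2008-12-31, 10 alphanumeric characters).

## Numerical choices

* Stabilizer $\varepsilon = 10^{-12}$ in the update denominators;
  initialization Uniform(0,1) under a caller-supplied seed; defaults
  `max_iter = 500`, relative-change tolerance `1e-4`. Restarts
  (`n_restarts`) keep the best final objective.
* `R >= M` is rejected: the factorization must reduce the dimension.
* An all-zero patient row folds in to the all-zero loading exactly (it
  is a fixed point of the multiplicative update).
* Vocabulary order is lexicographic — column order is otherwise
  arbitrary, and determinism matters for seeded reproducibility.
* Zero-denominator metrics (a fold with no cases) are `NA` and flagged
  `undefined`, never silently zero.
* Ties in `grid_search()` go to smaller $C$, then smaller $\gamma$ (the
  least complex model among equals).

## What the synthetic generator emulates — and what it does not

`generate_synthetic_emr()` plants $k$ latent disease themes: each theme
activates about `theme_code_sparsity * M` codes with Uniform(0.5, 1.5)
loadings, each patient draws Gamma(4, 4) theme weights (moderate
heterogeneity, coefficient of variation 0.5) scaled by `intensity`, and
case patients' weights on the designated risk themes are multiplied by
`case_theme_boost`. Entries of the binary matrix are
$\mathrm{Bernoulli}\!\left(1 - e^{-(PR_{\mathrm{true}}
DR_{\mathrm{true}}^{\top})_{n,m}}\right)$ — a presence observation of
an underlying intensity, keeping the matrix binary while preserving
approximate low-rank structure. The matrix is then expanded into dated
visit records (extra visits Poisson-distributed, dates uniform in the
window, target diagnoses for cases placed after all non-target records
so censoring reproduces the planted history), a registry file, and
injected malformed records at `noise_rate`.

Default study conditions: 500 cases / 500 controls (a balanced analysis
sample of a disease whose population prevalence is in the 0.1% regime),
$M = 400$ codes, $k = 5$ themes of which 2 are case-enriched with a
three-fold boost, a nine-year window, and 1% noise records. The
two-of-five enrichment and the Gamma(4, 4) dispersion were fixed at
generator-design time so that the planted signal is actually
identifiable: with a single enriched theme and high-dispersion
Gamma(2, 2) weights, the Bayes-optimal classifier on the *true* weights
tops out near 0.77 accuracy, i.e. no pipeline could demonstrate
recovery on such data.

What the generator does **not** emulate: realistic ICD-9 code frequency
distributions (real claims are heavy-tailed with strong hierarchy),
comorbidity network structure, temporal trends within a history (dates
carry no signal, matching the time-agnostic matrix), inpatient or
prescription records, and coding drift. Passing end-to-end tests
therefore shows the pipeline recovers planted low-rank structure from
record-level data through every stage — it does not certify performance
on real claims.

## Problem sizes used in the checks

The shipped validation suite runs the full record-level pipeline at
$N = 1000$, $M = 400$, $R = 5$ under inductive 10-fold CV (mean
sensitivity and specificity are required to reach 0.85, and permuted
labels must fall back to chance); multiplicative-update traces are
verified against the reference implementation on 100 random matrices up
to $50 \times 40$ at ranks up to 10; exact-rank recovery is checked for
$k \in \{1, 2, 5\}$ products. The acceptance script
(`scripts/acceptance.R`) additionally builds a 5,000-patient
registry-scale cohort in the 0.1% prevalence regime and runs a small
rank sweep. These sizes were chosen as the smallest at which the
statistical claims are stable across seeds.

## Known limitations

* The SVM operating point ($C$, $\gamma$) was selected for loading
  spaces of this kind; on new cohorts rerun `grid_search()` rather than
  trusting the defaults.
* Multiplicative updates converge slowly near the optimum; for exact
  rank recovery the suite uses restarts and generous iteration budgets.
  KL-divergence and sparsity-regularized NMF variants are out of scope.
* `select_R()` implements one defensible reading of a loosely stated
  selection rule; with very flat sweeps the gap filter can exclude all
  rows (it then warns).
* Cohort arms are not matched on age or sex, and no incidence-density
  sampling is performed; `summarize_cohort()` reports descriptive
  between-arm statistics only.
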