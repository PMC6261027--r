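test_that("stratified folds balance classes and partition the cohort", {
  # divisible case: every fold gets exactly 3 cases and 7 controls
  labs <- rep(c("case", "control"), c(30, 70))
  f <- stratified_kfold(labs, k = 10, seed = 4)
  expect_equal(sort(unique(f)), 1:10)
  tab <- table(labs, f)
  expect_true(all(tab["case", ] == 3))
  expect_true(all(tab["control", ] == 7))

  # remainder case: 13 cases over 10 folds differ by at most 1
  labs2 <- rep(c("case", "control"), c(13, 41))
  f2 <- stratified_kfold(labs2, k = 10, seed = 4)
  tab2 <- table(labs2, f2)
  expect_lte(max(tab2["case", ]) - min(tab2["case", ]), 1)
  expect_lte(max(tab2["control", ]) - min(tab2["control", ]), 1)
  expect_equal(length(f2), length(labs2))  # every patient in one fold

  # determinism and error handling
  expect_identical(stratified_kfold(labs, 10, seed = 4), f)
  expect_error(stratified_kfold(labs[1:5], k = 10), "exceeds")
  expect_error(stratified_kfold(labs, k = 1), "at least 2")
})

test_that("fold stratification balances across many label mixes", {
  set.seed(90)
  for (trial in 1:20) {
    n_case <- sample(3:40, 1); n_ctrl <- sample(10:80, 1)
    k <- sample(2:min(10, n_case + n_ctrl), 1)
    labs <- sample(rep(c("case", "control"), c(n_case, n_ctrl)))
    f <- stratified_kfold(labs, k = k, seed = trial)
    tab <- table(factor(labs), factor(f, levels = seq_len(k)))
    expect_true(all(apply(tab, 1, function(r) max(r) - min(r) <= 1)))
    expect_equal(sum(tab), length(labs))
  }
})

test_that("confusion metrics follow the sensitivity/specificity/accuracy formulas", {
  # TP=5 of CP=10 -> sensitivity 0.5
  truth <- rep(c("case", "control"), c(10, 10))
  pred <- c(rep("case", 5), rep("control", 5), rep("control", 10))
  m <- compute_metrics(truth, pred)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1)
  expect_equal(m$true_positive, 5)
  expect_equal(m$condition_positive, 10)

  # perfect prediction
  p <- compute_metrics(truth, truth)
  expect_equal(c(p$sensitivity, p$specificity, p$accuracy), c(1, 1, 1))

  # balanced classes: accuracy = (sens + spec) / 2; here 0.8/0.6 -> 0.7
  pred2 <- c(rep("case", 8), rep("control", 2),
             rep("control", 6), rep("case", 4))
  m2 <- compute_metrics(truth, pred2)
  expect_equal(m2$sensitivity, 0.8)
  expect_equal(m2$specificity, 0.6)
  expect_equal(m2$accuracy, 0.7)
  expect_equal(m2$accuracy, (m2$sensitivity + m2$specificity) / 2)

  # permutation invariance
  ord <- sample(20)
  m3 <- compute_metrics(truth[ord], pred2[ord])
  expect_equal(m3$accuracy, m2$accuracy)
  expect_equal(m3$sensitivity, m2$sensitivity)

  # zero denominators are flagged, not silently zero
  m4 <- compute_metrics(rep("control", 4), rep("control", 4))
  expect_true(is.na(m4$sensitivity))
  expect_true("sensitivity" %in% m4$undefined)
})

test_that("aggregation uses arithmetic means and the population SD", {
  fm <- function(acc) structure(list(true_positive = 0, true_negative = 0,
                                     condition_positive = 1,
                                     condition_negative = 1,
                                     sensitivity = acc, specificity = acc,
                                     accuracy = acc),
                                class = "fold_metrics")
  # population SD of {2, 4}: mean 3, SD 1 (divide by N)
  r <- aggregate_metrics(list(fm(2), fm(4)))
  expect_equal(r$mean$accuracy, 3)
  expect_equal(r$sd$accuracy, 1)
  # constant folds -> SD 0
  expect_equal(aggregate_metrics(list(fm(1), fm(1)))$sd$accuracy, 0)
  # hand case {1,2,3,4}: SD = sqrt(1.25)
  r4 <- aggregate_metrics(lapply(1:4, fm))
  expect_equal(r4$sd$accuracy, sqrt(1.25))
  expect_equal(population_sd(1:4), sqrt(1.25))
})

test_that("cross-validation runs inductively and transductively on planted data", {
  cfg <- synth_config(n_cases = 30, n_controls = 30, vocab_size = 80,
                      k_themes = 3, seed = 17)
  pdm <- pdm_from_planted(planted_factor_matrix(cfg))
  for (mode in c("inductive", "transductive")) {
    res <- run_cv(pdm, R = 3, folds = 5, seed = 8, mode = mode,
                  max_iter = 150, tol = 1e-4, pooled = TRUE)
    expect_equal(res$n_folds, 5L)
    for (m in c("sensitivity", "specificity", "accuracy")) {
      expect_gte(res$mean[[m]], 0); expect_lte(res$mean[[m]], 1)
      expect_gte(res$sd[[m]], 0)
    }
    expect_s3_class(res$pooled, "fold_metrics")
    expect_equal(res$pooled$condition_positive, 30)
  }
})

test_that("grouped-control evaluation partitions controls disjointly", {
  cfg <- synth_config(n_cases = 12, n_controls = 48, vocab_size = 60,
                      k_themes = 3, seed = 23)
  pdm <- pdm_from_planted(planted_factor_matrix(cfg))
  out <- grouped_control_evaluation(
    pdm, n_groups = 2, group_size = 20,
    protocol = function(sub, seed) {
      run_cv(sub, R = 3, folds = 3, seed = seed, max_iter = 100,
             tol = 1e-4)
    }, seed = 6)
  expect_length(out$results, 2L)
  expect_length(intersect(out$groups[[1]], out$groups[[2]]), 0L)
  expect_equal(length(unlist(out$groups)), 40L)
  expect_true(all(pdm$labels[unlist(out$groups)] == "control"))
  for (m in c("sensitivity", "specificity", "accuracy")) {
    expect_gte(out$grand$mean[[m]], 0); expect_lte(out$grand$mean[[m]], 1)
  }
  # same seed -> identical grouping
  out2 <- grouped_control_evaluation(
    pdm, n_groups = 2, group_size = 20,
    protocol = function(sub, seed) {
      structure(list(per_fold = list(), mean = list(sensitivity = 0,
        specificity = 0, accuracy = 0), sd = list(sensitivity = 0,
        specificity = 0, accuracy = 0), n_folds = 0, seed = seed),
        class = "eval_result")
    }, seed = 6)
  expect_identical(out$groups, out2$groups)
  expect_error(grouped_control_evaluation(pdm, n_groups = 5,
                                          group_size = 20), "controls")
})

test_that("evaluation results serialize to YAML and per-fold CSV", {
  truth <- rep(c("case", "control"), each = 5)
  res <- aggregate_metrics(list(compute_metrics(truth, truth)), seed = 3)
  ypath <- tempfile(fileext = ".yaml"); cpath <- tempfile(fileext = ".csv")
  write_eval_result(res, ypath, cpath)
  y <- yaml::read_yaml(ypath)
  expect_equal(y$mean$accuracy, 1)
  expect_equal(read.csv(cpath)$sensitivity, 1)
})
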