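test_that("stratified folds balance sizes overall and per class", {
  x <- generate_cohort(synthetic_config(seed = 2))  # 32 Pos / 51 Neg
  fold <- stratified_folds(x, k = 10, seed = 1)
  expect_equal(sort(unique(fold)), 1:10)
  sizes <- tabulate(fold, 10)
  expect_true(all(sizes %in% 8:9))
  pos_per_fold <- tabulate(fold[x$MRDx == "Pos"], 10)
  expect_true(all(pos_per_fold %in% 3:4))
  # every record in exactly one test fold
  expect_equal(length(fold), nrow(x))

  # leave-one-out
  loo <- stratified_folds(x, k = nrow(x), seed = 1)
  expect_equal(sort(loo), 1:nrow(x))

  # different seeds permute membership but keep the size constraints
  f2 <- stratified_folds(x, k = 10, seed = 2)
  expect_false(identical(fold, f2))
  expect_true(all(tabulate(f2, 10) %in% 8:9))

  expect_error(stratified_folds(x, k = 100, seed = 1), "k must")
})

test_that("confusion metrics match hand-computed values", {
  all_right <- confusion_metrics(c("Pos", "Neg"), c("Pos", "Neg"), "Pos")
  expect_equal(unlist(all_right[c("accuracy", "sensitivity", "specificity")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  all_wrong <- confusion_metrics(c("Pos", "Neg"), c("Neg", "Pos"), "Pos")
  expect_equal(all_wrong$accuracy, 0)

  # 32 Pos / 51 Neg with 25 TP, 7 FN, 50 TN, 1 FP
  truth <- c(rep("Pos", 32), rep("Neg", 51))
  pred <- c(rep("Pos", 25), rep("Neg", 7), rep("Neg", 50), rep("Pos", 1))
  m <- confusion_metrics(truth, pred, "Pos")
  expect_equal(round(100 * m$accuracy, 1), 90.4)
  expect_equal(100 * m$sensitivity, 78.13, tolerance = 1e-4)
  expect_gte(m$specificity, 0.980)
  expect_lte(m$specificity, 0.981)
})

test_that("the midrank AUC equals the all-pairs oracle, including ties", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c("P", "P", "N", "N"), "P"), 1.0)
  expect_equal(auc(rep(0.5, 10), rep(c("P", "N"), 5), "P"), 0.5)
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(10:200, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    y <- sample(c("P", "N"), n, replace = TRUE)
    y[1:2] <- c("P", "N")
    expect_equal(auc(s, y, "P"), auc_brute_force(s, y, "P"))
  }
  expect_error(auc(c(1, 2), c("P", "P"), "P"), "both classes")
})

test_that("cross-validation recovers a strong synthetic signal", {
  x <- generate_cohort(synthetic_config(n_pos = 320, n_neg = 510, seed = 1))
  cv <- cross_validate(x, k = 10)
  expect_gt(cv$pooled$accuracy, 0.75)
  expect_gt(cv$pooled$auc, 0.75)
  expect_equal(sum(cv$per_fold$n), nrow(x))
  expect_equal(cv$pooled$tp + cv$pooled$fp + cv$pooled$tn + cv$pooled$fn, nrow(x))
})

test_that("cross-validation on a null cohort stays near the majority rate", {
  cfg <- synthetic_config(n_pos = 64, n_neg = 102, seed = 9,
                          mde_rate_pos = 0.2, mde_rate_neg = 0.2,
                          effect_map = numeric(0))
  x <- generate_cohort(cfg)
  cv <- cross_validate(x, k = 10, seed = 3)
  majority <- 102 / 166
  se <- sqrt(majority * (1 - majority) / nrow(x))
  expect_lt(abs(cv$pooled$accuracy - majority), 3 * se)
})

test_that("tiny inputs cross-validate without error", {
  x <- cohort_table(data.frame(A = c("0", "1", "0", "1"),
                               MRDx = c("Pos", "Pos", "Neg", "Neg"),
                               stringsAsFactors = FALSE), "MRDx")
  cv <- cross_validate(x, k = 2, seed = 1)
  expect_s3_class(cv, "cv_report")
  expect_equal(nrow(cv$predictions), 4)
})

test_that("per-fold cut-points are fit on training rows only", {
  x <- generate_cohort(synthetic_config(seed = 33))
  cv <- cross_validate(x, k = 5, seed = 7)
  fold <- stratified_folds(x, k = 5, seed = 7)
  # re-fit EBD on fold 1's training rows: must equal the stored fold schemes
  train <- brlearn:::cohort_rows(x, which(fold != 1))
  refit <- discretize_cohort(train, ebd_config(lambda = 3.5))$schemes
  expect_equal(lapply(refit, function(s) s$thresholds), cv$fold_schemes[[1]])
  # and at least one variable's cut-points differ from the full-table fit
  full <- discretize_cohort(x, ebd_config(lambda = 3.5))$schemes
  same <- vapply(names(full), function(v)
    identical(full[[v]]$thresholds, cv$fold_schemes[[1]][[v]]), logical(1))
  expect_false(all(same))
})

test_that("the lambda sweep returns the lowest lambda among ties", {
  # an all-categorical table makes every lambda equivalent
  x <- strong_mde_table(n = 40, seed = 10)
  sw <- lambda_sweep(x, k = 4, seed = 2)
  expect_equal(sw$lambda, 0.5)
  expect_equal(length(sw$accuracy), 8)
  expect_true(all(abs(sw$accuracy - sw$accuracy[1]) < 1e-12))
  one <- lambda_sweep(x, grid = 3.5, k = 4, seed = 2)
  expect_equal(one$lambda, 3.5)
  expect_error(lambda_sweep(x, grid = numeric(0)), "non-empty")
})
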