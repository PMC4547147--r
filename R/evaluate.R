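#' Stratified cross-validation folds
#'
#' Class-stratified partition of the records into k folds: within each class
#' members are shuffled and dealt cyclically, always filling the currently
#' least-filled folds first, so fold sizes differ by at most one both per
#' class and overall. Deterministic given the seed.
#'
#' @param x a [cohort_table].
#' @param k number of folds (2 <= k <= n).
#' @param seed RNG seed.
#' @return integer vector of fold ids (1..k), one per record.
#' @export
stratified_folds <- function(x, k, seed = 20150813) {
  n <- nrow(x)
  if (k < 2 || k > n) stopf("k must satisfy 2 <= k <= n (= %d)", n)
  tf <- target_factor(x)
  set.seed(seed)
  fold <- integer(n)
  fill <- integer(k)
  for (cl in levels(tf)) {
    idx <- which(as.character(tf) == cl)
    idx <- idx[sample.int(length(idx))]
    ord <- order(fill, seq_len(k))        # least-filled folds first
    assign <- rep(ord, length.out = length(idx))
    fold[idx] <- assign
    fill <- fill + tabulate(assign, k)
  }
  fold
}

#' Confusion-matrix metrics
#'
#' @param truth true class labels.
#' @param predictions predicted class labels.
#' @param positive the positive class label.
#' @return list with \code{accuracy}, \code{sensitivity} (recall of the
#'   positive class), \code{specificity}, and the confusion counts
#'   \code{tp}, \code{fp}, \code{tn}, \code{fn}.
#' @export
confusion_metrics <- function(truth, predictions, positive) {
  stopifnot(length(truth) == length(predictions), length(truth) > 0)
  truth <- as.character(truth); predictions <- as.character(predictions)
  tp <- sum(truth == positive & predictions == positive)
  fn <- sum(truth == positive & predictions != positive)
  tn <- sum(truth != positive & predictions != positive)
  fp <- sum(truth != positive & predictions == positive)
  list(accuracy = (tp + tn) / length(truth),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Area under the ROC curve
#'
#' Mann-Whitney statistic with midrank tie handling:
#' P(score_pos > score_neg) + P(score_pos = score_neg) / 2 over all
#' positive-negative pairs, computed from midranks in O(n log n).
#'
#' @param scores numeric positive-class scores.
#' @param labels class labels.
#' @param positive the positive class label.
#' @return the AUC in \[0, 1\].
#' @export
auc <- function(scores, labels, positive) {
  stopifnot(length(scores) == length(labels))
  pos <- as.character(labels) == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stopf("AUC requires both classes present")
  r <- rank(scores)                       # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validate a rule learner
#'
#' Stratified k-fold protocol: within each fold the continuous predictors are
#' discretized by EBD on the training split only (set
#' \code{pooled_cuts = TRUE} to fit the discretization once on the full
#' table instead), a rule model is learned and annotated on the training
#' split, and the held-out records are scored. Metrics are reported per fold
#' and pooled over the concatenated held-out predictions.
#'
#' @param x a [cohort_table].
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param search \code{"tree"} or \code{"global"}.
#' @param lambda EBD prior weight.
#' @param max_parents,max_depth search limits.
#' @param pooled_cuts if TRUE, fit cut-points once on the full table
#'   (held-out rows then inform the discretization; default FALSE).
#' @return an object of class \code{cv_report}: fields \code{k}, \code{seed},
#'   \code{lambda}, \code{search}, \code{per_fold} (data.frame),
#'   \code{pooled} (accuracy, auc, sensitivity, specificity, confusion),
#'   \code{predictions} (per-record data.frame), and \code{fold_schemes}
#'   (per-fold cut-point thresholds, for leakage auditing).
#' @export
cross_validate <- function(x, k = 10, seed = 20150813, search = c("tree", "global"),
                           lambda = 3.5, max_parents = 8, max_depth = 8,
                           pooled_cuts = FALSE) {
  search <- match.arg(search)
  fold <- stratified_folds(x, k, seed)
  tf <- target_factor(x)
  pos <- positive_label(x)

  pooled_disc <- if (pooled_cuts) discretize_cohort(x, ebd_config(lambda = lambda)) else NULL
  preds <- data.frame(row = integer(0), fold = integer(0), truth = character(0),
                      class = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  fold_schemes <- vector("list", k)
  per_fold <- vector("list", k)

  for (f in seq_len(k)) {
    tr_idx <- which(fold != f); te_idx <- which(fold == f)
    train <- cohort_rows(x, tr_idx)
    if (pooled_cuts) {
      disc_train <- list(cohort = cohort_rows(pooled_disc$cohort, tr_idx),
                         schemes = pooled_disc$schemes)
    } else {
      disc_train <- discretize_cohort(train, ebd_config(lambda = lambda))
    }
    model <- if (search == "tree") {
      tree <- brl_tree_search(disc_train$cohort, max_depth = max_depth)
      tree_to_rules(tree, disc_train$cohort, schemes = disc_train$schemes)
    } else {
      brl_global_search(disc_train$cohort, max_parents = max_parents,
                        schemes = disc_train$schemes)
    }
    test <- cohort_rows(x, te_idx)
    p <- predict(model, test)
    truth <- as.character(tf)[te_idx]
    cm <- confusion_metrics(truth, p$class, pos)
    fold_auc <- if (length(unique(truth)) == 2L) auc(p$score, truth, pos) else NA_real_
    per_fold[[f]] <- data.frame(fold = f, n = length(te_idx),
                                accuracy = cm$accuracy, auc = fold_auc,
                                tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn)
    fold_schemes[[f]] <- lapply(disc_train$schemes, function(s) s$thresholds)
    preds <- rbind(preds, data.frame(row = te_idx, fold = f, truth = truth,
                                     class = p$class, score = p$score,
                                     stringsAsFactors = FALSE))
  }

  cm <- confusion_metrics(preds$truth, preds$class, pos)
  pooled <- list(accuracy = cm$accuracy,
                 auc = auc(preds$score, preds$truth, pos),
                 sensitivity = cm$sensitivity, specificity = cm$specificity,
                 tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn)
  structure(list(k = k, seed = seed, lambda = lambda, search = search,
                 per_fold = do.call(rbind, per_fold), pooled = pooled,
                 predictions = preds, fold_schemes = fold_schemes),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s search, lambda = %s, seed = %d)\n",
              x$k, x$search, fmt_num(x$lambda), x$seed))
  cat(sprintf("pooled: accuracy = %.2f%%, AUC = %.1f%%, sensitivity = %.2f%%, specificity = %.2f%%\n",
              100 * x$pooled$accuracy, 100 * x$pooled$auc,
              100 * x$pooled$sensitivity, 100 * x$pooled$specificity))
  invisible(x)
}

#' Select the EBD prior weight by cross-validation
#'
#' Evaluates each lambda of the grid by [cross_validate] and returns the
#' lowest lambda achieving the maximal pooled accuracy (pooled AUC breaks
#' accuracy ties; remaining ties go to the lower lambda).
#'
#' @param x a [cohort_table].
#' @param grid lambdas to evaluate, default \code{seq(0.5, 4.0, by = 0.5)}.
#' @param k,seed,... passed to [cross_validate].
#' @return list with \code{lambda} (the choice), \code{accuracy} (named
#'   vector over the grid) and \code{reports} (named list of
#'   \code{cv_report}s).
#' @export
lambda_sweep <- function(x, grid = seq(0.5, 4.0, by = 0.5), k = 10,
                         seed = 20150813, ...) {
  if (!length(grid)) stopf("lambda grid must be non-empty")
  reports <- lapply(grid, function(l) cross_validate(x, k = k, seed = seed,
                                                     lambda = l, ...))
  names(reports) <- fmt_num(grid)
  acc <- vapply(reports, function(r) r$pooled$accuracy, numeric(1))
  aucs <- vapply(reports, function(r) r$pooled$auc, numeric(1))
  best_acc <- max(acc)
  cand <- which(acc >= best_acc - 1e-12)
  cand <- cand[aucs[cand] >= max(aucs[cand]) - 1e-12]
  choice <- min(grid[cand])               # lowest qualifying lambda wins
  list(lambda = choice, accuracy = stats::setNames(acc, fmt_num(grid)),
       reports = reports)
}
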