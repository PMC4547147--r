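# independent oracles and fixture builders used across the suite

# exhaustive enumeration over all cut subsets (EBD oracle, feasible for B <= 12)
ebd_brute_force <- function(values, labels, lambda) {
  cand <- candidate_boundaries(values, labels)
  B <- length(cand)
  best <- -Inf; best_thr <- numeric(0)
  for (mask in 0:(2^B - 1)) {
    thr <- cand[bitwAnd(mask, 2^(seq_len(B) - 1)) > 0]
    sch <- cut_scheme(thr)
    f <- apply_scheme(values, sch)
    sc <- -length(thr) * log(lambda) +
      sum(vapply(levels(f), function(l)
        interval_log_score(table(factor(labels)[f == l])), numeric(1)))
    if (sc > best + 1e-9) { best <- sc; best_thr <- thr }
  }
  list(score = best, thresholds = best_thr)
}

# naive candidate midpoints: loop over adjacent distinct values, compare class
# multisets directly
candidate_brute_force <- function(values, labels) {
  ord <- order(values)
  v <- values[ord]; l <- labels[ord]
  uv <- sort(unique(v))
  out <- numeric(0)
  for (i in seq_len(length(uv) - 1)) {
    a <- sort(l[v == uv[i]]); b <- sort(l[v == uv[i + 1]])
    if (length(a) != length(b) || any(a != b))
      out <- c(out, (uv[i] + uv[i + 1]) / 2)
  }
  out
}

# all-pairs AUC with half credit for ties
auc_brute_force <- function(scores, labels, positive) {
  ps <- scores[labels == positive]; ns <- scores[labels != positive]
  mean(outer(ps, ns, ">") + 0.5 * outer(ps, ns, "=="))
}

# best achievable leaf-score sum over all trees of depth <= 2 (independent
# recursion: each subtree optimized exhaustively)
best_tree_score_depth2 <- function(x) {
  tf <- x[[target_name(x)]]
  preds <- predictor_names(x)
  leaf_sc <- function(idx) interval_log_score(tabulate(tf[idx], nlevels(tf)))
  rec <- function(idx, unused, depth) {
    best <- leaf_sc(idx)
    if (depth < 2) for (v in unused) {
      sc <- sum(vapply(levels(x[[v]]), function(l)
        rec(idx & x[[v]] == l, setdiff(unused, v), depth + 1), numeric(1)))
      best <- max(best, sc)
    }
    best
  }
  rec(rep(TRUE, nrow(x)), preds, 0)
}

# random records over a cohort's roster (continuous values beyond the
# observed range on purpose)
random_records <- function(x, n, seed) {
  set.seed(seed)
  cols <- lapply(predictor_names(x), function(v) {
    if (variable_kind(x, v) == "continuous") {
      r <- range(x[[v]]); w <- max(diff(r), 1)
      stats::runif(n, r[1] - w, r[2] + w)
    } else sample(variable_levels(x, v), n, replace = TRUE)
  })
  stats::setNames(as.data.frame(cols, stringsAsFactors = FALSE),
                  predictor_names(x))
}

# categorical-only view of a synthetic cohort (demographics, MDE, ranges)
categorical_view <- function(x) {
  keep <- c("MDE", "Gender", "LVEDVR", "LVESVR", "RVEDVR", "RVESVR", "SVR",
            target_name(x))
  cohort_table(as.data.frame(x)[keep], target_name(x),
               positive = positive_label(x))
}

# small all-categorical cohort with a strong binary driver:
# MDE = Yes forces Pos, everything else is noise
strong_mde_table <- function(n = 60, seed = 4) {
  set.seed(seed)
  mde <- sample(c("Yes", "No"), n, replace = TRUE)
  noise1 <- sample(c("a", "b"), n, replace = TRUE)
  noise2 <- sample(c("x", "y", "z"), n, replace = TRUE)
  cls <- ifelse(mde == "Yes", "Pos",
                sample(c("Pos", "Neg"), n, replace = TRUE, prob = c(0.2, 0.8)))
  cohort_table(data.frame(MDE = mde, N1 = noise1, N2 = noise2, MRDx = cls,
                          stringsAsFactors = FALSE), "MRDx", positive = "Pos")
}

# random small all-categorical table with 3 binary predictors
random_binary_table <- function(n, seed) {
  set.seed(seed)
  d <- data.frame(A = sample(c("lo", "hi"), n, TRUE),
                  B = sample(c("lo", "hi"), n, TRUE),
                  C = sample(c("lo", "hi"), n, TRUE),
                  MRDx = sample(c("Pos", "Neg"), n, TRUE),
                  stringsAsFactors = FALSE)
  # guarantee both classes
  d$MRDx[1] <- "Pos"; d$MRDx[2] <- "Neg"
  cohort_table(d, "MRDx", positive = "Pos")
}

# the printed evidence statistics of the 13-rule demonstration model, keyed
# by a compact condition signature
demo_expected_stats <- function() {
  data.frame(
    signature = c(
      "MDE=Yes",
      "MDE=No,RVESVR=Low,RVEF=(33.7 to 57]",
      "MDE=No,RVESVR=Normal,LVEDVR=Normal,LVESVR=Normal,SVI=≤ 67",
      "MDE=No,RVESVR=Normal,LVEDVR=Low",
      "MDE=No,RVESVR=Normal,LVEDVR=Normal,LVESVR=High",
      "MDE=No,RVESVR=Low,RVEF=> 57,LVEDVR=Normal",
      "MDE=No,RVESVR=Low,RVEF=> 57,LVEDVR=Low",
      "MDE=No,RVESVR=Low,RVEF=≤ 33.7",
      "MDE=No,RVESVR=Low,RVEF=> 57,LVEDVR=High",
      "MDE=No,RVESVR=Normal,LVEDVR=Normal,LVESVR=Low",
      "MDE=No,RVESVR=Normal,LVEDVR=High",
      "MDE=No,RVESVR=High",
      "MDE=No,RVESVR=Normal,LVEDVR=Normal,LVESVR=Normal,SVI=> 67"),
    predicted = c("Pos", rep("Neg", 8), rep("Pos", 4)),
    tp = c(17, 5, 22, 16, 3, 2, 2, 0, 0, 3, 2, 2, 1),
    fp = c(1, 0, 3, 2, 0, 0, 2, 0, 0, 0, 0, 0, 0),
    prob = c(0.9, 0.857, 0.852, 0.85, 0.8, 0.75, 0.5, 0.5, 0.5, 0.8, 0.75, 0.75, 0.667),
    p = c(0.0, 0.081, 0.001, 0.005, 0.227, 0.375, 0.843, 1.0, 1.0, 0.054, 0.146, 0.146, 0.386),
    stringsAsFactors = FALSE)
}

rule_signature <- function(rule) {
  paste(sprintf("%s=%s", rule$conditions$variable, rule$conditions$value),
        collapse = ",")
}
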