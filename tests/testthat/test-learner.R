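test_that("the partition score is the sum of per-group Dirichlet scores", {
  expect_equal(bayes_score(factor("Pos", levels = c("Pos", "Neg")), "g"), log(1 / 2))
  cls <- factor(c("Pos", "Neg"), levels = c("Pos", "Neg"))
  expect_equal(bayes_score(cls, c("g1", "g2")), 2 * log(1 / 2))
  expect_equal(bayes_score(cls, c("g", "g")), interval_log_score(c(1, 1)))
})

test_that("global search picks the dominant predictor first and max_parents=1 is the exhaustive argmax", {
  x <- strong_mde_table(n = 80, seed = 4)
  m <- brl_global_search(x)
  expect_equal(attr(m, "trace")$variable[1], "MDE")

  m1 <- brl_global_search(x, max_parents = 1)
  tf <- x[[target_name(x)]]
  scan <- vapply(predictor_names(x), function(v) bayes_score(tf, x[[v]]), numeric(1))
  expect_equal(m1$selected_variables, names(which.max(scan)))
})

test_that("global models carry a catch-all rule and match unseen combinations", {
  x <- strong_mde_table(n = 40, seed = 9)
  m <- brl_global_search(x)
  expect_true(m$rules[[length(m$rules)]]$is_default)
  rec <- random_records(x, 500, seed = 1)
  p <- predict(m, rec)
  expect_equal(nrow(p), 500)
  expect_true(all(p$posterior > 0 & p$posterior < 1))
})

test_that("a pure-class table yields a single leaf", {
  x <- cohort_table(data.frame(A = c("a", "b", "a"), MRDx = c("Neg", "Neg", "Neg2"),
                               stringsAsFactors = FALSE), "MRDx", positive = "Neg2")
  x2 <- cohort_rows(x, 1:2)  # only Neg remains
  tree <- brl_tree_search(x2)
  expect_equal(tree$kind, "leaf")
})

test_that("a strong MDE effect is recovered at the tree root with a Pos leaf", {
  x <- strong_mde_table(n = 100, seed = 6)
  tree <- brl_tree_search(x)
  expect_equal(tree$kind, "split")
  expect_equal(tree$variable, "MDE")
  yes <- tree$children[["Yes"]]
  expect_equal(yes$kind, "leaf")
  expect_equal(yes$predicted, "Pos")
})

test_that("the greedy tree never beats (and often equals) the exhaustive depth-2 optimum", {
  equal_cases <- 0
  for (seed in 1:20) {
    x <- random_binary_table(n = sample(8:20, 1), seed = seed)
    tree <- brl_tree_search(x, max_depth = 2)
    greedy <- brlearn:::tree_score(tree)
    best <- best_tree_score_depth2(x)
    expect_lte(greedy, best + 1e-9)
    if (abs(greedy - best) < 1e-9) equal_cases <- equal_cases + 1
  }
  expect_gte(equal_cases, 10)
})

test_that("tree-derived rules are mutually exclusive, exhaustive and conserve counts", {
  for (seed in c(2, 11, 23)) {
    x <- categorical_view(generate_cohort(synthetic_config(seed = seed)))
    tree <- brl_tree_search(x)
    model <- tree_to_rules(tree, x)
    # every random record matches exactly one rule (match_rules errors otherwise)
    rec <- random_records(x, 2000, seed = seed)
    expect_equal(length(brlearn:::match_rules(model, rec)), 2000)
    # leaf-count conservation
    total <- Reduce(`+`, lapply(model$rules, function(r) r$tp + r$fp))
    expect_equal(total, nrow(x))
    tf <- x[[target_name(x)]]
    pos_total <- sum(vapply(model$rules, function(r)
      if (r$predicted_class == "Pos") r$tp else r$fp, numeric(1)))
    expect_equal(pos_total, sum(tf == "Pos"))
  }
})

test_that("a single-leaf tree becomes one unconditional rule covering everything", {
  x <- strong_mde_table(n = 30, seed = 2)
  leaf_tree <- brl_tree_search(x, max_depth = 0)
  model <- tree_to_rules(leaf_tree, x)
  expect_equal(length(model$rules), 1L)
  expect_equal(nrow(model$rules[[1]]$conditions), 0L)
  expect_equal(model$rules[[1]]$tp + model$rules[[1]]$fp, 30L)
})

test_that("greedy steps strictly increase the Bayesian score", {
  x <- categorical_view(generate_cohort(synthetic_config(seed = 15)))
  for (kind in c("tree", "global")) {
    m <- if (kind == "tree") tree_to_rules(brl_tree_search(x), x)
         else brl_global_search(x)
    tr <- attr(m, "trace")
    expect_gt(nrow(tr), 0)
    expect_true(all(tr$score_after > tr$score_before))
  }
})

test_that("learning is deterministic given the input", {
  x <- generate_cohort(synthetic_config(seed = 21))
  m1 <- brl_learn(x, search = "tree")
  m2 <- brl_learn(x, search = "tree")
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_rule_model_json(m1, f1); write_rule_model_json(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a table with no predictors degrades to a single majority rule", {
  x <- cohort_table(data.frame(MRDx = c("Pos", "Neg", "Neg")), "MRDx")
  m <- brl_global_search(x)
  expect_equal(length(m$rules), 1L)
  expect_equal(m$rules[[1]]$predicted_class, "Neg")
})
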