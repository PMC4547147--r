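test_that("the Laplace posterior reproduces every printed rule probability", {
  exp <- demo_expected_stats()
  expect_equal(round(rule_posterior(exp$tp, exp$fp), 3), round(exp$prob, 3))
  expect_equal(rule_posterior(0, 0), 0.5)
  # strictly increasing in tp, decreasing in fp
  expect_true(all(diff(rule_posterior(0:20, 3)) > 0))
  expect_true(all(diff(rule_posterior(5, 0:20)) < 0))
})

test_that("the one-sided Fisher exact p reproduces every printed rule p-value", {
  exp <- demo_expected_stats()
  n_pos <- 32; n_neg <- 51
  for (i in seq_len(nrow(exp))) {
    npc <- if (exp$predicted[i] == "Pos") n_pos else n_neg
    p <- rule_fisher_p(exp$tp[i], exp$fp[i], npc, n_pos + n_neg - npc)
    if (exp$p[i] == 0) expect_lte(p, 5e-4)
    else expect_equal(round(p, 3), exp$p[i])
  }
})

test_that("the Fisher p agrees with fisher.test across random contingency settings", {
  set.seed(14)
  for (rep in 1:30) {
    K <- sample(5:120, 1); M <- sample(5:80, 1)
    if (K + M > 200) next
    d <- sample(0:(K + M), 1)
    tp <- sample(0:min(K, d), 1); fp <- d - tp
    if (fp > M) next
    ours <- rule_fisher_p(tp, fp, K, M)
    tab <- matrix(c(tp, fp, K - tp, M - fp), nrow = 2, byrow = TRUE)
    oracle <- stats::fisher.test(tab, alternative = "greater")$p.value
    expect_equal(ours, oracle, tolerance = 1e-9)
  }
  expect_equal(rule_fisher_p(0, 0, 51, 32), 1.0)
})

test_that("rule coverage counts matching records against the predicted class", {
  x <- strong_mde_table(n = 50, seed = 3)
  tf <- x[[target_name(x)]]
  uncond <- brl_rule(NULL, "Pos")
  cov <- rule_coverage(uncond, x)
  expect_equal(cov$tp, sum(tf == "Pos"))
  expect_equal(cov$fp, sum(tf == "Neg"))
  expect_error(brl_rule(data.frame(variable = c("MDE", "MDE"),
                                   value = c("Yes", "No")), "Pos"),
               "distinct")
  r <- brl_rule(data.frame(variable = "MDE", value = "Purple"), "Pos")
  expect_error(rule_coverage(r, x, levels_map = list(MDE = c("No", "Yes"))),
               "not a level")
})

test_that("annotating the demonstration model on its implanted cohort reproduces the printed statistics", {
  model <- cardiomyopathy_demo_model()
  cfg <- implant_rule_model(synthetic_config(seed = 101), model)
  x <- generate_cohort(cfg)
  ann <- annotate_model(model, x)
  exp <- demo_expected_stats()
  for (r in ann$rules) {
    i <- match(rule_signature(r), exp$signature)
    expect_false(is.na(i))
    expect_equal(r$tp, exp$tp[i])
    expect_equal(r$fp, exp$fp[i])
    expect_equal(round(r$posterior, 3), exp$prob[i])
    if (exp$p[i] == 0) expect_lte(r$p_value, 5e-4)
    else expect_equal(round(r$p_value, 3), exp$p[i])
  }
})

test_that("prediction returns the unique matching rule's class and posterior", {
  model <- cardiomyopathy_demo_model()
  cfg <- implant_rule_model(synthetic_config(seed = 55), model)
  x <- generate_cohort(cfg)
  model <- annotate_model(model, x)

  mde_yes <- x[x$MDE == "Yes", ][1, ]
  p <- predict(model, mde_yes)
  expect_equal(p$class, "Pos")
  expect_equal(p$posterior, 0.9)
  expect_equal(positive_score(model, mde_yes), 0.9)

  # a record satisfying the five conditions of the large Neg rule
  r2 <- Filter(function(r) r$tp == 22, model$rules)[[1]]
  hit <- which(brlearn:::rule_matches(r2, x, model$schemes))
  p2 <- predict(model, x[hit[1], ])
  expect_equal(p2$class, "Neg")
  expect_equal(round(p2$posterior, 3), 0.852)
  expect_equal(round(p2$score, 3), 0.148)
})

test_that("annotated statistics always lie in their open ranges", {
  for (seed in c(5, 17)) {
    x <- categorical_view(generate_cohort(synthetic_config(seed = seed)))
    m <- tree_to_rules(brl_tree_search(x), x)
    for (r in m$rules) {
      expect_true(r$posterior > 0 && r$posterior < 1)
      expect_true(r$p_value > 0 && r$p_value <= 1)
      expect_equal(r$posterior, (r$tp + 1) / (r$tp + r$fp + 2))
    }
  }
})
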