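test_that("candidate boundaries are class-change midpoints", {
  expect_equal(candidate_boundaries(c(1, 2, 3, 4), c("A", "A", "B", "B")), 2.5)
  expect_equal(candidate_boundaries(c(5, 1, 9), c("A", "A", "A")), numeric(0))
  expect_equal(candidate_boundaries(rep(3, 4), c("A", "B", "A", "B")), numeric(0))
  set.seed(31)
  for (rep in 1:20) {
    v <- sample(round(rnorm(20), 1))  # duplicates likely
    l <- sample(c("A", "B"), 20, replace = TRUE)
    expect_equal(candidate_boundaries(v, l), candidate_brute_force(v, l))
  }
})

test_that("interval score is the Dirichlet(1) log marginal likelihood", {
  expect_equal(interval_log_score(c(0, 0)), 0)
  expect_equal(interval_log_score(c(1, 0)), log(1 / 2))
  # chain rule of sequential predictive probabilities for counts (2, 2)
  seq_prob <- 1
  counts <- c(0, 0)
  for (cls in c(1, 1, 2, 2)) {
    seq_prob <- seq_prob * (counts[cls] + 1) / (sum(counts) + 2)
    counts[cls] <- counts[cls] + 1
  }
  expect_equal(interval_log_score(c(2, 2)), log(seq_prob))
})

test_that("the EBD dynamic program matches exhaustive enumeration", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(6:14, 1)
    v <- round(rnorm(n), 1)
    l <- sample(c("A", "B"), n, replace = TRUE)
    lam <- sample(c(0.5, 1, 2, 3.5), 1)
    sch <- ebd_discretize(v, l, ebd_config(lambda = lam))
    bf <- ebd_brute_force(v, l, lam)
    expect_equal(attr(sch, "score"), bf$score, tolerance = 1e-10)
    expect_equal(sch$thresholds, bf$thresholds, tolerance = 1e-12)
  }
})

test_that("the number of intervals is non-increasing in lambda", {
  set.seed(5)
  v <- rnorm(60); l <- sample(c("Pos", "Neg"), 60, replace = TRUE)
  ni <- vapply(c(0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 10, 1e9), function(lam)
    length(ebd_discretize(v, l, ebd_config(lambda = lam))$thresholds), numeric(1))
  expect_true(all(diff(ni) <= 0))
  expect_equal(ni[length(ni)], 0)  # a dominating prior yields one interval
})

test_that("a separable two-cluster input gets exactly the class boundary cut", {
  v <- c(1, 2, 3, 11, 12, 13)
  l <- c("A", "A", "A", "B", "B", "B")
  sch <- ebd_discretize(v, l, ebd_config(lambda = 0.5))
  expect_equal(sch$thresholds, 7)
})

test_that("the total score decomposes into prior plus interval scores", {
  set.seed(8)
  v <- rnorm(30); l <- sample(c("A", "B"), 30, replace = TRUE)
  lam <- 2.5
  sch <- ebd_discretize(v, l, ebd_config(lambda = lam))
  f <- apply_scheme(v, sch)
  manual <- -length(sch$thresholds) * log(lam) +
    sum(vapply(levels(f), function(lev)
      interval_log_score(table(factor(l)[f == lev])), numeric(1)))
  expect_equal(attr(sch, "score"), manual)
})

test_that("swapping class labels leaves the chosen thresholds unchanged", {
  set.seed(12)
  for (rep in 1:10) {
    v <- rnorm(25); l <- sample(c("A", "B"), 25, replace = TRUE)
    s1 <- ebd_discretize(v, l, ebd_config(lambda = 1.5))
    s2 <- ebd_discretize(v, ifelse(l == "A", "B", "A"), ebd_config(lambda = 1.5))
    expect_equal(s1$thresholds, s2$thresholds)
  }
})

test_that("max_intervals caps the scheme and stays optimal under the cap", {
  v <- c(1, 2, 10, 11, 20, 21, 30, 31)
  l <- c("A", "A", "B", "B", "A", "A", "B", "B")
  s_free <- ebd_discretize(v, l, ebd_config(lambda = 0.5))
  expect_equal(length(s_free$thresholds), 3)
  s_cap <- ebd_discretize(v, l, ebd_config(lambda = 0.5, max_intervals = 2))
  expect_lte(length(s_cap$thresholds), 1)
})

test_that("scheme application uses left-open right-closed intervals", {
  sch <- cut_scheme(c(33.7, 57), "RVEF")
  expect_equal(sch$labels, c("≤ 33.7", "(33.7 to 57]", "> 57"))
  out <- as.character(apply_scheme(c(57, 33.7, 33.71, 100, -5), sch))
  expect_equal(out, c("(33.7 to 57]", "≤ 33.7", "(33.7 to 57]", "> 57", "≤ 33.7"))
  one <- cut_scheme(numeric(0), "X")
  expect_equal(unique(as.character(apply_scheme(rnorm(10), one))), "all")
  expect_error(apply_scheme(c(1, NaN), sch), "non-finite")
})
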