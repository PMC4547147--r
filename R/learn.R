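#' Classification rules
#'
#' A rule is a conjunction of variable = value conditions over categorical
#' (or discretized) predictors, a predicted target class, and evidence
#' statistics: covered true positives \code{tp} (records matching the
#' conditions whose class equals the prediction), false positives \code{fp}
#' (matching records of the other class), the Laplace posterior
#' \code{(tp + 1) / (tp + fp + 2)}, and a one-sided Fisher exact p-value.
#'
#' @param conditions a data.frame with columns \code{variable} and
#'   \code{value} (possibly zero rows for an unconditional rule). Condition
#'   variables must be distinct.
#' @param predicted_class the predicted target level.
#' @param tp,fp coverage counts (filled by [annotate_model] when \code{NA}).
#' @param p_value one-sided Fisher exact p (filled by [annotate_model]).
#' @param is_default marks the catch-all rule emitted by the global search
#'   for parent-value combinations unseen in training.
#' @return an object of class \code{brl_rule}. The posterior is always
#'   derived from \code{tp} and \code{fp}.
#' @export
brl_rule <- function(conditions, predicted_class, tp = NA_integer_, fp = NA_integer_,
                     p_value = NA_real_, is_default = FALSE) {
  if (is.null(conditions) || nrow(conditions) == 0L) {
    conditions <- data.frame(variable = character(0), value = character(0),
                             stringsAsFactors = FALSE)
  }
  conditions$variable <- unname(as.character(conditions$variable))
  conditions$value <- unname(as.character(conditions$value))
  rownames(conditions) <- NULL
  if (anyDuplicated(conditions$variable))
    stopf("rule conditions must reference distinct variables (duplicate '%s')",
          conditions$variable[duplicated(conditions$variable)][1L])
  structure(list(conditions = conditions[, c("variable", "value")],
                 predicted_class = as.character(predicted_class),
                 tp = as.integer(tp), fp = as.integer(fp),
                 posterior = if (is.na(tp)) NA_real_ else rule_posterior(tp, fp),
                 p_value = as.numeric(p_value),
                 is_default = isTRUE(is_default)),
            class = "brl_rule")
}

#' Rule models
#'
#' An ordered set of mutually exclusive and exhaustive rules: every possible
#' record matches exactly one rule, and that rule alone makes the prediction.
#' Models learned from discretized data carry the cut-point schemes used, so
#' they can be applied directly to raw continuous records.
#'
#' @param rules list of [brl_rule]s.
#' @param target target variable name.
#' @param positive positive class label.
#' @param levels_map named list: condition variable -> its full level set
#'   (used for exhaustiveness checking and tree export).
#' @param schemes named list of [cut_scheme]s for continuous condition
#'   variables.
#' @param search_kind \code{"global"} or \code{"tree"}.
#' @return an object of class \code{brl_model}; \code{selected_variables}
#'   is the union of condition variables.
#' @export
brl_model <- function(rules, target, positive, levels_map = list(),
                      schemes = list(), search_kind = c("tree", "global")) {
  search_kind <- match.arg(search_kind)
  structure(list(rules = rules, target = target, positive = positive,
                 levels_map = levels_map, schemes = schemes,
                 search_kind = search_kind,
                 selected_variables = sort(unique(unlist(lapply(
                   rules, function(r) r$conditions$variable))))),
            class = "brl_model")
}

#' @export
print.brl_model <- function(x, digits = 3, ...) {
  cat(format_rule_model(x, digits = digits), sep = "\n")
  invisible(x)
}

# condition value of a record set, as interval label for continuous columns
condition_column <- function(data, variable, schemes, kinds = NULL) {
  v <- data[[variable]]
  if (is.null(v)) stopf("record lacks variable '%s'", variable)
  if (is.numeric(v)) {
    sch <- schemes[[variable]]
    if (is.null(sch)) stopf("no cut-point scheme for continuous variable '%s'", variable)
    as.character(apply_scheme(v, sch))
  } else as.character(v)
}

# logical vector: which rows of `data` satisfy every condition of `rule`
rule_matches <- function(rule, data, schemes = list(), levels_map = list()) {
  n <- nrow(data)
  hit <- rep(TRUE, n)
  conds <- rule$conditions
  for (i in seq_len(nrow(conds))) {
    col <- condition_column(data, conds$variable[i], schemes)
    known <- levels_map[[conds$variable[i]]]
    if (!is.null(known) && !conds$value[i] %in% known)
      stopf("condition value '%s' is not a level of '%s'", conds$value[i], conds$variable[i])
    hit <- hit & (col == conds$value[i])
  }
  hit
}

# index of the unique matching rule per row; errors on 0 or >1 matches
match_rules <- function(model, data) {
  n <- nrow(data)
  rules <- model$rules
  default_i <- which(vapply(rules, function(r) r$is_default, logical(1)))
  mat <- vapply(seq_along(rules), function(i) {
    if (i %in% default_i) rep(FALSE, n)
    else rule_matches(rules[[i]], data, model$schemes, model$levels_map)
  }, logical(n))
  mat <- matrix(mat, nrow = n)
  hits <- rowSums(mat)
  if (length(default_i)) {
    mat[, default_i[1L]] <- hits == 0L
    hits <- hits + (hits == 0L)
  }
  if (any(hits != 1L)) {
    bad <- which(hits != 1L)[1L]
    stopf("record %d matched %d rules; the model violates mutual exclusivity/exhaustiveness",
          bad, hits[bad])
  }
  max.col(mat)
}

#' Bayesian score of a class partition
#'
#' The K2-style log marginal likelihood of the target given a partition of
#' the records into groups: the sum over groups of each group's Dirichlet(1)
#' class-count score ([interval_log_score]). Decomposable over groups, so a
#' tree's score is the sum of its leaf scores.
#'
#' @param classes class labels (factor or character).
#' @param groups grouping vector of the same length (a partition).
#' @return the log score.
#' @export
bayes_score <- function(classes, groups) {
  stopifnot(length(classes) == length(groups))
  classes <- as.factor(classes)
  C <- nlevels(classes)
  if (length(classes) == 0L) return(0)
  counts <- table(groups, classes)
  sum(apply(counts, 1L, interval_log_score))
}

# class counts (positive first) of a record subset
class_counts <- function(tf, idx) tabulate(tf[idx], nlevels(tf))

# majority class with deterministic tie-break: group majority, then global
# majority, then the negative label
majority_class <- function(counts, global_counts, levels, negative) {
  pick <- function(cnt) {
    mx <- which(cnt == max(cnt))
    if (length(mx) == 1L) levels[mx] else NA_character_
  }
  g <- pick(counts)
  if (!is.na(g)) return(g)
  g <- pick(global_counts)
  if (!is.na(g)) return(g)
  negative
}

#' Global greedy rule search
#'
#' Greedily grows the target's parent set: starting from the empty set, each
#' iteration adds the predictor whose inclusion most increases the Bayesian
#' score of the partition induced by the observed joint parent values,
#' stopping when no addition strictly improves the score or \code{max_parents}
#' is reached. Emits one rule per observed parent-value combination (each rule
#' conditions on every parent) plus a default catch-all rule for unobserved
#' combinations, so the rule set is mutually exclusive and exhaustive.
#'
#' @param x an all-categorical [cohort_table] (discretize first, e.g. with
#'   [discretize_cohort]).
#' @param max_parents maximum number of parents (default 8).
#' @param schemes optional named list of [cut_scheme]s to attach to the model.
#' @return an annotated [brl_model] with \code{search_kind = "global"}. The
#'   attribute \code{"trace"} records each greedy step's variable and scores.
#' @export
brl_global_search <- function(x, max_parents = 8, schemes = list()) {
  stopifnot(max_parents >= 1)
  preds <- predictor_names(x)
  kinds <- attr(x, "kinds")
  if (any(unlist(kinds[preds]) != "categorical"))
    stopf("global search requires categorical predictors; discretize first")
  tf <- target_factor(x)
  lv <- levels(tf)
  global_counts <- tabulate(tf, nlevels(tf))

  parents <- character(0)
  part <- function(vars) {
    if (!length(vars)) return(factor(rep("", nrow(x))))
    interaction(lapply(vars, function(v) x[[v]]), drop = TRUE, lex.order = TRUE)
  }
  score <- bayes_score(tf, part(parents))
  trace <- data.frame(step = integer(0), variable = character(0),
                      score_before = numeric(0), score_after = numeric(0),
                      stringsAsFactors = FALSE)
  repeat {
    if (length(parents) >= max_parents) break
    cand <- setdiff(preds, parents)
    if (!length(cand)) break
    sc <- vapply(cand, function(v) bayes_score(tf, part(c(parents, v))), numeric(1))
    nlv <- vapply(cand, function(v) length(levels(x[[v]])), numeric(1))
    ord <- order(-sc, nlv, cand)
    best <- ord[1L]
    if (sc[best] <= score + .score_tol) break
    trace <- rbind(trace, data.frame(step = length(parents) + 1L,
                                     variable = cand[best],
                                     score_before = score, score_after = sc[best],
                                     stringsAsFactors = FALSE))
    parents <- c(parents, cand[best])
    score <- sc[best]
  }

  # one rule per observed combination, in lexicographic level order
  if (length(parents)) {
    combos <- unique(as.data.frame(lapply(parents, function(v) as.character(x[[v]])),
                                   col.names = parents, stringsAsFactors = FALSE))
    combos <- combos[do.call(order, combos), , drop = FALSE]
    rules <- lapply(seq_len(nrow(combos)), function(i) {
      keep <- rep(TRUE, nrow(x))
      for (v in parents) keep <- keep & (as.character(x[[v]]) == combos[[v]][i])
      cnt <- class_counts(tf, keep)
      brl_rule(data.frame(variable = parents, value = unlist(combos[i, ]),
                          stringsAsFactors = FALSE),
               predicted_class = majority_class(cnt, global_counts, lv, negative_label(x)))
    })
    rules <- c(rules, list(brl_rule(NULL,
      predicted_class = majority_class(global_counts, global_counts, lv, negative_label(x)),
      is_default = TRUE)))
  } else {
    rules <- list(brl_rule(NULL,
      predicted_class = majority_class(global_counts, global_counts, lv, negative_label(x))))
  }

  levels_map <- stats::setNames(lapply(preds, function(v) levels(x[[v]])), preds)
  model <- brl_model(rules, target = target_name(x), positive = positive_label(x),
                     levels_map = levels_map, schemes = schemes, search_kind = "global")
  model <- annotate_model(model, x)
  attr(model, "trace") <- trace
  model
}

#' Decision-tree local structure search
#'
#' Greedy Bayesian decision tree: at each node, every unused predictor is
#' evaluated as a split; the node's leaf score is replaced by the sum of its
#' children's leaf scores, and the split with the greatest strict score
#' improvement is taken. A node stops growing when it is pure, no split
#' improves the score, or the depth limit is reached. Each child covers one
#' level of the split variable, so the induced rules are mutually exclusive
#' and exhaustive.
#'
#' @param x an all-categorical [cohort_table].
#' @param max_depth maximum tree depth (default 8; 0 forces a single leaf).
#' @return an object of class \code{brl_tree}: nested nodes, each either
#'   \code{list(kind = "split", variable, children)} or
#'   \code{list(kind = "leaf", counts, predicted)}, with \code{counts} named
#'   by target level. Attribute \code{"trace"} records the greedy splits.
#' @export
brl_tree_search <- function(x, max_depth = 8) {
  stopifnot(max_depth >= 0)
  preds <- predictor_names(x)
  kinds <- attr(x, "kinds")
  if (any(unlist(kinds[preds]) != "categorical"))
    stopf("tree search requires categorical predictors; discretize first")
  tf <- target_factor(x)
  lv <- levels(tf)
  global_counts <- stats::setNames(tabulate(tf, nlevels(tf)), lv)
  trace <- new.env(parent = emptyenv()); trace$log <- list()

  grow <- function(idx, unused, depth) {
    cnt <- stats::setNames(class_counts(tf, idx), lv)
    leaf <- list(kind = "leaf", counts = cnt,
                 predicted = majority_class(cnt, global_counts, lv, negative_label(x)))
    leaf_score <- interval_log_score(cnt)
    if (depth >= max_depth || !length(unused) || sum(cnt > 0) <= 1L)
      return(leaf)
    gains <- vapply(unused, function(v) {
      sum(vapply(levels(x[[v]]), function(lev) {
        interval_log_score(class_counts(tf, idx & (x[[v]] == lev)))
      }, numeric(1))) - leaf_score
    }, numeric(1))
    nlv <- vapply(unused, function(v) length(levels(x[[v]])), numeric(1))
    ord <- order(-gains, nlv, unused)
    best <- ord[1L]
    if (gains[best] <= .score_tol) return(leaf)
    v <- unused[best]
    trace$log[[length(trace$log) + 1L]] <-
      data.frame(variable = v, depth = depth, n = sum(idx),
                 score_before = leaf_score, score_after = leaf_score + gains[best],
                 stringsAsFactors = FALSE)
    children <- lapply(levels(x[[v]]), function(lev) {
      grow(idx & (x[[v]] == lev), setdiff(unused, v), depth + 1L)
    })
    list(kind = "split", variable = v,
         children = stats::setNames(children, levels(x[[v]])))
  }

  tree <- grow(rep(TRUE, nrow(x)), preds, 0L)
  tree <- structure(tree, class = "brl_tree",
                    target = target_name(x), positive = positive_label(x),
                    levels = lv)
  attr(tree, "trace") <- do.call(rbind, trace$log) %||%
    data.frame(variable = character(0), depth = integer(0), n = integer(0),
               score_before = numeric(0), score_after = numeric(0))
  tree
}

#' @export
print.brl_tree <- function(x, ...) {
  rec <- function(node, prefix) {
    if (node$kind == "leaf") {
      cat(sprintf("%s-> %s (%s)\n", prefix, node$predicted,
                  paste(sprintf("%s=%d", names(node$counts), node$counts), collapse = ", ")))
    } else {
      cat(sprintf("%s[%s]\n", prefix, node$variable))
      for (lev in names(node$children)) {
        cat(sprintf("%s  %s = %s:\n", prefix, node$variable, lev))
        rec(node$children[[lev]], paste0(prefix, "    "))
      }
    }
  }
  rec(unclass(x), "")
  invisible(x)
}

# total Bayesian score of a tree (sum of leaf scores)
tree_score <- function(tree) {
  rec <- function(node) {
    if (node$kind == "leaf") interval_log_score(node$counts)
    else sum(vapply(node$children, rec, numeric(1)))
  }
  rec(unclass(tree))
}

#' Convert a decision tree to a rule model
#'
#' Each root-to-leaf path becomes one rule whose conditions are the variable
#' assignments along the path and whose prediction is the leaf's majority
#' class (ties go to the globally more frequent class, then the negative
#' label). The resulting rules are annotated with coverage, posterior and
#' Fisher p against \code{x}.
#'
#' @param tree a \code{brl_tree}.
#' @param x the [cohort_table] used for annotation (categorical, or raw
#'   continuous if \code{schemes} supplied).
#' @param schemes optional named list of [cut_scheme]s attached to the model.
#' @return an annotated [brl_model] with \code{search_kind = "tree"}.
#' @export
tree_to_rules <- function(tree, x, schemes = list()) {
  rules <- list()
  levels_map <- list()
  rec <- function(node, conds) {
    if (node$kind == "leaf") {
      rules[[length(rules) + 1L]] <<- brl_rule(conds, predicted_class = node$predicted)
    } else {
      levels_map[[node$variable]] <<- names(node$children)
      for (lev in names(node$children)) {
        rec(node$children[[lev]],
            rbind(conds, data.frame(variable = node$variable, value = lev,
                                    stringsAsFactors = FALSE)))
      }
    }
  }
  rec(unclass(tree), data.frame(variable = character(0), value = character(0),
                                stringsAsFactors = FALSE))
  model <- brl_model(rules, target = attr(tree, "target"),
                     positive = attr(tree, "positive"),
                     levels_map = levels_map, schemes = schemes,
                     search_kind = "tree")
  model <- annotate_model(model, x)
  attr(model, "trace") <- attr(tree, "trace")
  model
}

#' Learn a rule model end to end
#'
#' Convenience wrapper: discretizes the continuous predictors with EBD, runs
#' the requested search on the categorical table, attaches the cut-point
#' schemes, and annotates the rules against the training data.
#'
#' @param x a [cohort_table].
#' @param search \code{"tree"} (decision-tree local structure) or
#'   \code{"global"} (parent-set search).
#' @param lambda EBD prior weight (default 3.5).
#' @param max_parents,max_depth search limits (default 8).
#' @return an annotated [brl_model].
#' @export
brl_learn <- function(x, search = c("tree", "global"), lambda = 3.5,
                      max_parents = 8, max_depth = 8) {
  search <- match.arg(search)
  disc <- discretize_cohort(x, ebd_config(lambda = lambda))
  if (search == "tree") {
    tree <- brl_tree_search(disc$cohort, max_depth = max_depth)
    model <- tree_to_rules(tree, disc$cohort, schemes = disc$schemes)
  } else {
    model <- brl_global_search(disc$cohort, max_parents = max_parents,
                               schemes = disc$schemes)
  }
  model
}
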