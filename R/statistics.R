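#' Laplace posterior probability of a rule
#'
#' Beta(1, 1)-posterior mean of the probability that a record covered by the
#' rule belongs to the predicted class: \code{(tp + 1) / (tp + fp + 2)}. A
#' rule covering no records is maximally uncertain (0.5).
#'
#' @param tp,fp non-negative coverage counts.
#' @return a probability strictly inside (0, 1).
#' @export
rule_posterior <- function(tp, fp) {
  stopifnot(all(tp >= 0), all(fp >= 0))
  (tp + 1) / (tp + fp + 2)
}

#' One-sided Fisher exact p-value of a rule
#'
#' Upper-tail hypergeometric probability of drawing at least \code{tp}
#' predicted-class records when \code{tp + fp} covered records are drawn
#' without replacement from a cohort with \code{n_pred_class} records of the
#' predicted class and \code{n_other} of the other class:
#' \deqn{P = \sum_{x \ge tp} \frac{\binom{K}{x}\binom{N-K}{d-x}}{\binom{N}{d}}}
#' with \eqn{N = n_{pred} + n_{other}}, \eqn{K = n_{pred}}, \eqn{d = tp + fp}.
#' Computed by exact log-gamma arithmetic.
#'
#' @param tp,fp coverage counts; may instead pass a list with fields
#'   \code{tp}, \code{fp}, \code{n_pred_class}, \code{n_other} as \code{tp}.
#' @param n_pred_class,n_other class totals in the cohort.
#' @return the exact p-value in (0, 1].
#' @export
rule_fisher_p <- function(tp, fp = NULL, n_pred_class = NULL, n_other = NULL) {
  if (is.list(tp)) {
    counts <- tp
    tp <- counts$tp; fp <- counts$fp
    n_pred_class <- counts$n_pred_class; n_other <- counts$n_other
  }
  stopifnot(tp >= 0, fp >= 0, tp <= n_pred_class, fp <= n_other)
  d <- tp + fp
  if (d == 0L || tp == 0L) return(1.0)
  N <- n_pred_class + n_other
  x <- tp:min(n_pred_class, d)
  logp <- lchoose(n_pred_class, x) + lchoose(n_other, d - x) - lchoose(N, d)
  min(1.0, sum(exp(logp)))
}

#' Coverage counts of a rule
#'
#' A record is covered iff it satisfies every condition of the rule;
#' covered records are tallied as \code{tp} (record class equals the rule's
#' prediction) or \code{fp} (other class). Class totals of the whole table
#' are returned alongside for the Fisher test.
#'
#' @param rule a [brl_rule].
#' @param x a [cohort_table].
#' @param schemes named list of [cut_scheme]s for continuous condition
#'   variables.
#' @param levels_map optional named list of declared levels for validation.
#' @return a list with \code{tp}, \code{fp}, \code{n_pred_class},
#'   \code{n_other}.
#' @export
rule_coverage <- function(rule, x, schemes = list(), levels_map = list()) {
  tf <- target_factor(x)
  lv <- levels(tf)
  if (!rule$predicted_class %in% lv)
    stopf("predicted class '%s' is not a target level", rule$predicted_class)
  covered <- rule_matches(rule, x, schemes, levels_map)
  pred_is <- as.character(tf) == rule$predicted_class
  list(tp = sum(covered & pred_is), fp = sum(covered & !pred_is),
       n_pred_class = sum(pred_is), n_other = sum(!pred_is))
}

#' Annotate a rule model with evidence statistics
#'
#' Computes tp, fp, the Laplace posterior and the one-sided Fisher exact p
#' for every rule against \code{x}. The default catch-all rule of a global
#' model covers exactly the records matched by no other rule.
#'
#' @param model a [brl_model].
#' @param x a [cohort_table].
#' @return the model with all rule statistics filled in.
#' @export
annotate_model <- function(model, x) {
  tf <- target_factor(x)
  rules <- model$rules
  default_i <- which(vapply(rules, function(r) r$is_default, logical(1)))
  matched <- rep(FALSE, nrow(x))
  cov <- vector("list", length(rules))
  for (i in seq_along(rules)) {
    if (i %in% default_i) next
    hit <- rule_matches(rules[[i]], x, model$schemes, model$levels_map)
    matched <- matched | hit
    cov[[i]] <- hit
  }
  for (i in default_i) cov[[i]] <- !matched
  model$rules <- lapply(seq_along(rules), function(i) {
    r <- rules[[i]]
    pred_is <- as.character(tf) == r$predicted_class
    tp <- sum(cov[[i]] & pred_is); fp <- sum(cov[[i]] & !pred_is)
    r$tp <- as.integer(tp); r$fp <- as.integer(fp)
    r$posterior <- rule_posterior(tp, fp)
    r$p_value <- rule_fisher_p(tp, fp, sum(pred_is), sum(!pred_is))
    r
  })
  model
}

#' Predict with a rule model
#'
#' Finds, for each record, the unique matching rule (mutual exclusivity is
#' enforced: zero or multiple matches raise an error) and returns its
#' predicted class and posterior, plus a positive-class score: the rule's
#' posterior when it predicts the positive class, otherwise its complement.
#'
#' @param object a [brl_model] with annotated rules.
#' @param newdata a data.frame or [cohort_table] supplying every variable the
#'   model uses (raw continuous columns are discretized through the model's
#'   schemes).
#' @param ... unused.
#' @return a data.frame with columns \code{class}, \code{posterior},
#'   \code{score} and \code{rule} (index of the matching rule).
#' @export
predict.brl_model <- function(object, newdata, ...) {
  idx <- match_rules(object, newdata)
  post <- vapply(object$rules, function(r) r$posterior, numeric(1))
  pred <- vapply(object$rules, function(r) r$predicted_class, character(1))
  if (anyNA(post[idx])) stopf("model is not annotated; call annotate_model() first")
  data.frame(class = pred[idx], posterior = post[idx],
             score = ifelse(pred[idx] == object$positive, post[idx], 1 - post[idx]),
             rule = idx, stringsAsFactors = FALSE)
}

#' Positive-class score of records under a rule model
#'
#' @inheritParams predict.brl_model
#' @param model a [brl_model].
#' @return numeric vector in \[0, 1\]: the matching rule's posterior if it
#'   predicts the positive class, else one minus it.
#' @export
positive_score <- function(model, newdata) {
  predict(model, newdata)$score
}
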