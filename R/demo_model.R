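#' Reference 13-rule cardiomyopathy demonstration model
#'
#' A hand-built Bayesian decision tree over the synthetic roster, shipped for
#' demonstrations and validation of the tree-to-rules conversion, the
#' evidence statistics and the implanting generator. Its root splits on MDE
#' status (MDE present predicts a positive finding); MDE-negative patients
#' descend through RV end-systolic volume range, RV ejection fraction
#' (cut-points 33.7 and 57 %), LV volume ranges and stroke volume index
#' (cut-point 67 ml/m^2), yielding 13 mutually exclusive, exhaustive rules —
#' 8 predicting Neg and 5 predicting Pos — over a 32 positive / 51 negative
#' cohort. Two of its leaves cover no records and fall back to the majority
#' class with posterior 0.5.
#'
#' @return \code{cardiomyopathy_demo_tree()}: a \code{brl_tree};
#'   \code{cardiomyopathy_demo_model()}: the corresponding annotated
#'   [brl_model], including the RVEF and SVI cut-point schemes.
#' @export
cardiomyopathy_demo_tree <- function() {
  leaf <- function(pos, neg, predicted = NULL) {
    cnt <- c(Pos = pos, Neg = neg)
    if (is.null(predicted)) predicted <- if (pos > neg) "Pos" else "Neg"
    list(kind = "leaf", counts = cnt, predicted = predicted)
  }
  split <- function(variable, children) list(kind = "split", variable = variable,
                                             children = children)
  rvef_labels <- interval_labels_from_thresholds(c(33.7, 57))
  svi_labels <- interval_labels_from_thresholds(67)

  rvef_low_tree <- split("RVEF", stats::setNames(list(
    leaf(0, 0, "Neg"),                                   # RVEF <= 33.7, no evidence
    leaf(0, 5),                                          # RVEF in (33.7, 57]
    split("LVEDVR", list(Low = leaf(2, 2, "Neg"),        # tie -> majority class
                         Normal = leaf(0, 2),
                         High = leaf(0, 0, "Neg")))
  ), rvef_labels))

  svi_tree <- split("SVI", stats::setNames(list(leaf(3, 22), leaf(1, 0)), svi_labels))
  lvesvr_tree <- split("LVESVR", list(Low = leaf(3, 0), Normal = svi_tree,
                                      High = leaf(0, 3)))
  rvesvr_normal_tree <- split("LVEDVR", list(Low = leaf(2, 16),
                                             Normal = lvesvr_tree,
                                             High = leaf(2, 0)))
  tree <- split("MDE", list(
    No = split("RVESVR", list(Low = rvef_low_tree,
                              Normal = rvesvr_normal_tree,
                              High = leaf(2, 0))),
    Yes = leaf(17, 1)))
  structure(tree, class = "brl_tree", target = "MRDx", positive = "Pos",
            levels = c("Pos", "Neg"),
            trace = data.frame(variable = character(0), depth = integer(0),
                               n = integer(0), score_before = numeric(0),
                               score_after = numeric(0)))
}

#' @rdname cardiomyopathy_demo_tree
#' @export
cardiomyopathy_demo_model <- function() {
  tree <- cardiomyopathy_demo_tree()
  rules <- list(); levels_map <- list()
  rec <- function(node, conds) {
    if (node$kind == "leaf") {
      tp <- node$counts[[node$predicted]]
      fp <- sum(node$counts) - tp
      rules[[length(rules) + 1L]] <<- brl_rule(conds, node$predicted,
                                               tp = tp, fp = fp)
    } else {
      levels_map[[node$variable]] <<- names(node$children)
      for (lev in names(node$children))
        rec(node$children[[lev]],
            rbind(conds, data.frame(variable = node$variable, value = lev,
                                    stringsAsFactors = FALSE)))
    }
  }
  rec(unclass(tree), data.frame(variable = character(0), value = character(0),
                                stringsAsFactors = FALSE))
  n_pos <- 32L; n_neg <- 51L
  rules <- lapply(rules, function(r) {
    npc <- if (r$predicted_class == "Pos") n_pos else n_neg
    r$p_value <- rule_fisher_p(r$tp, r$fp, npc, n_pos + n_neg - npc)
    r
  })
  brl_model(rules,
            target = "MRDx", positive = "Pos", levels_map = levels_map,
            schemes = list(RVEF = cut_scheme(c(33.7, 57), "RVEF"),
                           SVI = cut_scheme(67, "SVI")),
            search_kind = "tree")
}
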