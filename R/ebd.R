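#' EBD configuration
#'
#' Settings for the supervised Bayesian discretizer. \code{lambda} is the
#' prior weight penalizing the number of intervals: a discretization with I
#' intervals receives a log-prior of \code{-(I - 1) * log(lambda)}, so larger
#' values favour fewer cut-points. \code{max_intervals} optionally caps the
#' number of intervals.
#'
#' @param lambda positive prior weight (default 3.5).
#' @param max_intervals positive integer cap on the number of intervals
#'   (default unbounded).
#' @return an object of class \code{ebd_config}.
#' @export
ebd_config <- function(lambda = 3.5, max_intervals = Inf) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stopf("lambda must be a single positive number")
  if (!(is.infinite(max_intervals) || (max_intervals >= 1 && max_intervals == floor(max_intervals))))
    stopf("max_intervals must be a positive integer or Inf")
  structure(list(lambda = lambda, max_intervals = max_intervals), class = "ebd_config")
}

#' Candidate cut-point boundaries
#'
#' Returns the midpoints between consecutive distinct sorted values whose
#' class compositions differ (class-boundary midpoints). Only such midpoints
#' can appear in an optimal supervised discretization, so they form the
#' candidate set for the dynamic program.
#'
#' @param values numeric series.
#' @param labels class labels, same length.
#' @return a numeric vector of strictly increasing thresholds (possibly empty).
#' @export
candidate_boundaries <- function(values, labels) {
  stopifnot(length(values) == length(labels), length(values) >= 1L)
  if (any(!is.finite(values))) stopf("values must be finite")
  labels <- as.character(labels)
  ord <- order(values)
  v <- values[ord]; l <- labels[ord]
  uv <- unique(v)
  if (length(uv) < 2L) return(numeric(0))
  # class count matrix per distinct value
  cls <- sort(unique(labels))
  cnt <- table(factor(v), factor(l, levels = cls))
  differ <- rowSums(abs(cnt[-1L, , drop = FALSE] - cnt[-nrow(cnt), , drop = FALSE])) > 0
  mid <- (uv[-1L] + uv[-length(uv)]) / 2
  mid[differ]
}

#' Bayesian score of one interval
#'
#' Log marginal likelihood of an interval's class column under a uniform
#' Dirichlet(1, ..., 1) prior:
#' \deqn{\log\left[\frac{\Gamma(C)}{\Gamma(C+N)} \prod_c \Gamma(1+n_c)\right]}
#' with C classes, per-class counts \eqn{n_c} and \eqn{N = \sum_c n_c}. The
#' same quantity scores a leaf of a rule model, so the total model score is a
#' sum of interval scores.
#'
#' @param class_counts non-negative integer counts, one per class.
#' @return the log score (0 for an empty interval).
#' @export
interval_log_score <- function(class_counts) {
  C <- length(class_counts)
  N <- sum(class_counts)
  lgamma(C) - lgamma(C + N) + sum(lgamma(1 + class_counts))
}

interval_labels_from_thresholds <- function(thresholds) {
  B <- length(thresholds)
  if (B == 0L) return("all")
  t <- fmt_num(thresholds)
  if (B == 1L) return(c(paste0("≤ ", t[1L]), paste0("> ", t[1L])))
  c(paste0("≤ ", t[1L]),
    paste0("(", t[-B], " to ", t[-1L], "]"),
    paste0("> ", t[B]))
}

#' Cut-point schemes
#'
#' A cut-point scheme maps a continuous variable to ordered interval labels.
#' Intervals are left-open right-closed: value v belongs to interval i iff
#' \code{thresholds[i-1] < v <= thresholds[i]}; the two open ends are rendered
#' \code{"≤ a"} and \code{"> b"}, interior intervals \code{"(a to b]"}.
#'
#' @param thresholds strictly increasing numeric vector (possibly empty).
#' @param variable optional variable name the scheme belongs to.
#' @return an object of class \code{cut_scheme} with fields \code{variable},
#'   \code{thresholds} and \code{labels} (length \code{length(thresholds) + 1}).
#' @export
cut_scheme <- function(thresholds = numeric(0), variable = NA_character_) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) && (any(!is.finite(thresholds)) || is.unsorted(thresholds, strictly = TRUE)))
    stopf("thresholds must be finite and strictly increasing")
  labels <- interval_labels_from_thresholds(thresholds)
  if (anyDuplicated(labels)) stopf("interval labels must be unique")
  structure(list(variable = variable, thresholds = thresholds, labels = labels),
            class = "cut_scheme")
}

#' @export
print.cut_scheme <- function(x, ...) {
  cat(sprintf("cut_scheme for '%s': %s\n", x$variable,
              paste(x$labels, collapse = " | ")))
  invisible(x)
}

#' Apply a cut-point scheme
#'
#' @param values numeric series (all finite).
#' @param scheme a [cut_scheme].
#' @return a factor over the scheme's interval labels.
#' @export
apply_scheme <- function(values, scheme) {
  if (any(!is.finite(values))) stopf("cannot discretize non-finite value")
  idx <- findInterval(values, scheme$thresholds, left.open = TRUE) + 1L
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Efficient Bayesian discretization
#'
#' Chooses cut-points for a continuous predictor by maximizing
#' \deqn{-(I-1)\log\lambda + \sum_{i=1}^{I} \mathrm{score}(interval_i)}
#' over all subsets of the candidate class-boundary midpoints, where each
#' interval's score is its Dirichlet(1) log marginal likelihood
#' ([interval_log_score]). The optimum is found by an O(B^2) dynamic program
#' over the B candidates. Ties (within 1e-9) are broken toward fewer
#' intervals, then earlier cut positions.
#'
#' @param values numeric series.
#' @param labels class labels (two classes).
#' @param config an [ebd_config].
#' @param variable optional name recorded in the returned scheme.
#' @return a [cut_scheme]; the attribute \code{"score"} carries the optimal
#'   total log score.
#' @export
ebd_discretize <- function(values, labels, config = ebd_config(), variable = NA_character_) {
  stopifnot(length(values) == length(labels), length(values) >= 1L)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  cand <- candidate_boundaries(values, labels)
  B <- length(cand)
  loglam <- log(config$lambda)

  # cumulative class counts at each boundary position (0..B+1); position j
  # covers all records with value <= cand[j] (position B+1: all records)
  cum <- matrix(0, nrow = B + 2L, ncol = length(cls))
  lab_f <- factor(labels, levels = cls)
  if (B > 0L) {
    for (j in seq_len(B)) cum[j + 1L, ] <- tabulate(lab_f[values <= cand[j]], length(cls))
  }
  cum[B + 2L, ] <- tabulate(lab_f, length(cls))

  seg_score <- function(i, j) { # vectorized over i
    d <- cum[rep(j, length(i)), , drop = FALSE] - cum[i, , drop = FALSE]
    lgamma(length(cls)) - lgamma(length(cls) + rowSums(d)) +
      rowSums(lgamma(1 + d))
  }

  if (is.finite(config$max_intervals) && config$max_intervals <= B) {
    # bounded variant: DP over (intervals used, end position)
    K <- as.integer(config$max_intervals)
    NEG <- -Inf
    dp <- matrix(NEG, nrow = K, ncol = B + 2L)  # dp[k, j]: best with k intervals ending at j
    bp <- matrix(0L, nrow = K, ncol = B + 2L)
    for (j in 2L:(B + 2L)) dp[1L, j] <- seg_score(1L, j)
    if (K > 1L) for (k in 2L:K) {
      for (j in (k + 1L):(B + 2L)) {
        i <- k:(j - 1L)
        candv <- dp[k - 1L, i] + seg_score(i, j)
        top <- max(candv)
        best <- which(candv >= top - .score_tol)[1L]  # tie: smaller i
        dp[k, j] <- candv[best]; bp[k, j] <- i[best]
      }
    }
    totals <- dp[, B + 2L] - (seq_len(K) - 1L) * loglam
    kbest <- which(totals >= max(totals) - .score_tol)[1L]
    cuts <- integer(0); j <- B + 2L; k <- kbest
    while (k > 1L) { i <- bp[k, j]; cuts <- c(i, cuts); j <- i; k <- k - 1L }
    thr <- if (length(cuts)) cand[cuts - 1L] else numeric(0)
    sc <- totals[kbest]
  } else {
    # unbounded O(B^2) DP; dp[j] = best total (penalties included) for data up
    # to boundary position j, where every segment end j <= B+1 is a cut
    dp <- rep(-Inf, B + 2L); nint <- rep(0L, B + 2L); bp <- rep(0L, B + 2L)
    dp[1L] <- 0
    for (j in 2L:(B + 2L)) {
      i <- 1L:(j - 1L)
      candv <- dp[i] + seg_score(i, j) - if (j <= B + 1L) loglam else 0
      top <- max(candv)
      tied <- which(candv >= top - .score_tol)
      best <- tied[which.min(nint[i][tied])]  # fewer intervals, then smaller i
      dp[j] <- candv[best]; nint[j] <- nint[i[best]] + 1L; bp[j] <- i[best]
    }
    cuts <- integer(0); j <- B + 2L
    while (bp[j] > 1L) { j <- bp[j]; cuts <- c(j, cuts) }
    thr <- if (length(cuts)) cand[cuts - 1L] else numeric(0)
    sc <- dp[B + 2L]
  }

  out <- cut_scheme(thr, variable = variable)
  attr(out, "score") <- sc
  out
}

#' Discretize all continuous predictors of a cohort
#'
#' Fits [ebd_discretize] per continuous predictor against the target and
#' replaces each with its interval factor; categorical predictors pass
#' through.
#'
#' @param x a [cohort_table].
#' @param config an [ebd_config].
#' @return a list with \code{cohort} (all-categorical [cohort_table]) and
#'   \code{schemes} (named list of [cut_scheme]s for the continuous
#'   predictors).
#' @export
discretize_cohort <- function(x, config = ebd_config()) {
  y <- as.character(target_factor(x))
  schemes <- list()
  out <- as.data.frame(x, stringsAsFactors = FALSE)
  kinds <- attr(x, "kinds")
  for (col in predictor_names(x)) {
    if (kinds[[col]] == "continuous") {
      sch <- ebd_discretize(x[[col]], y, config = config, variable = col)
      schemes[[col]] <- sch
      out[[col]] <- as.character(apply_scheme(x[[col]], sch))
      kinds[[col]] <- "categorical"
    } else {
      out[[col]] <- as.character(x[[col]])
    }
  }
  spec <- data.frame(name = predictor_names(x), kind = "categorical",
                     stringsAsFactors = FALSE)
  spec$levels <- lapply(predictor_names(x), function(col) {
    if (!is.null(schemes[[col]])) schemes[[col]]$labels else levels(x[[col]])
  })
  cohort <- cohort_table(out, target = target_name(x),
                         positive = positive_label(x), spec = spec)
  list(cohort = cohort, schemes = schemes)
}
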