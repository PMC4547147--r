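# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# score comparisons use an absolute tolerance: scores are sums of lgamma terms,
# so genuine ties (e.g. under label permutation) agree to ~1e-12
.score_tol <- 1e-9

fmt_num <- function(x) vapply(x, function(xi)
  format(xi, digits = 6, trim = TRUE, scientific = FALSE), character(1))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
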