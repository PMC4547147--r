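# rule-model serialization: a human-readable IF-THEN text format and a
# lossless JSON format

format_condition <- function(variable, value) {
  if (grepl("^(≤|>) ", value)) sprintf("(%s %s)", variable, value)
  else sprintf("(%s = %s)", variable, value)
}

format_rule_line <- function(rule, target) {
  lhs <- if (rule$is_default) "(OTHERWISE)"
  else if (nrow(rule$conditions) == 0L) "(TRUE)"
  else paste(mapply(format_condition, rule$conditions$variable,
                    rule$conditions$value), collapse = " & ")
  sprintf("IF %s THEN (%s = %s)", lhs, target, rule$predicted_class)
}

format_stats_line <- function(rule, digits = 3) {
  sprintf("Prob = %s, P = %s, TP = %d, FP = %d",
          format(round(rule$posterior, digits), nsmall = 0),
          format(round(rule$p_value, digits), nsmall = 0),
          rule$tp, rule$fp)
}

#' Format a rule model as IF-THEN text
#'
#' One pair of lines per rule: the rule in the clinical IF-THEN dialect
#' (interval conditions rendered \code{"(VAR = (a to b])"}, open-ended ones
#' \code{"(VAR ≤ a)"} / \code{"(VAR > b)"}), then its statistics
#' \code{Prob} (posterior, 3 decimals), \code{P} (Fisher p, 3 decimals),
#' \code{TP} and \code{FP}.
#'
#' @param model an annotated [brl_model].
#' @param digits decimals for the displayed Prob and P.
#' @return a character vector of lines.
#' @export
format_rule_model <- function(model, digits = 3) {
  lines <- c(sprintf("# target: %s | positive: %s | search: %s",
                     model$target, model$positive, model$search_kind))
  for (i in seq_along(model$rules)) {
    r <- model$rules[[i]]
    lines <- c(lines,
               sprintf("%d. %s", i, format_rule_line(r, model$target)),
               paste0("   ", format_stats_line(r, digits)))
  }
  lines
}

#' Write / read the text form of a rule model
#'
#' The text form mirrors the printed rule listing; statistics are rounded to
#' 3 decimals on write, so the round-trip preserves structure, predictions
#' and coverage counts exactly but Prob/P only to display precision. Use the
#' JSON form ([write_rule_model_json]) for a lossless round-trip.
#'
#' @param model an annotated [brl_model].
#' @param path file path.
#' @return \code{write_rule_model_text}: invisibly, \code{path};
#'   \code{read_rule_model_text}: a [brl_model] (without schemes).
#' @export
write_rule_model_text <- function(model, path) {
  writeLines(format_rule_model(model), path, useBytes = FALSE)
  invisible(path)
}

parse_condition_text <- function(txt, lineno) {
  txt <- trimws(txt)
  if (!grepl("^\\(", txt) || !grepl("\\)$", txt))
    stopf("malformed condition '%s' on line %d", txt, lineno)
  inner <- substr(txt, 2L, nchar(txt) - 1L)
  if (grepl(" ≤ | > ", inner) && !grepl(" = ", inner)) {
    m <- regmatches(inner, regexpr(" (≤|>) ", inner))
    at <- regexpr(" (≤|>) ", inner)
    variable <- substr(inner, 1L, at - 1L)
    value <- substr(inner, at + 1L, nchar(inner))
  } else {
    at <- regexpr(" = ", inner, fixed = TRUE)
    if (at < 0) stopf("malformed condition '%s' on line %d", txt, lineno)
    variable <- substr(inner, 1L, at - 1L)
    value <- substr(inner, at + 3L, nchar(inner))
  }
  data.frame(variable = variable, value = value, stringsAsFactors = FALSE)
}

#' @rdname write_rule_model_text
#' @export
read_rule_model_text <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  target <- "MRDx"; positive <- "Pos"; search_kind <- "tree"
  hdr <- grep("^# target:", lines, value = TRUE)
  if (length(hdr)) {
    m <- regmatches(hdr[1], regexec(
      "^# target: (\\S+) \\| positive: (\\S+) \\| search: (\\S+)", hdr[1]))[[1]]
    if (length(m) == 4L) { target <- m[2]; positive <- m[3]; search_kind <- m[4] }
  }
  lines_i <- which(grepl("^\\s*\\d*\\.?\\s*IF ", lines))
  rules <- list()
  for (li in lines_i) {
    line <- sub("^\\s*\\d+\\.\\s*", "", lines[li])
    m <- regmatches(line, regexec("^IF (.*) THEN \\((\\S+) = ([^)]+)\\)\\s*$", line))[[1]]
    if (length(m) != 4L) stopf("malformed rule on line %d: %s", li, lines[li])
    lhs <- m[2]; predicted <- m[4]
    is_default <- identical(lhs, "(OTHERWISE)")
    conds <- if (is_default || identical(lhs, "(TRUE)")) NULL
    else do.call(rbind, lapply(strsplit(lhs, " & ", fixed = TRUE)[[1]],
                               parse_condition_text, lineno = li))
    stats_line <- if (li < length(lines)) lines[li + 1L] else ""
    sm <- regmatches(stats_line, regexec(
      "Prob = ([0-9.eE+-]+), P = ([0-9.eE+-]+), TP = (\\d+), FP = (\\d+)", stats_line))[[1]]
    if (length(sm) != 5L) stopf("missing statistics line after rule on line %d", li)
    r <- brl_rule(conds, predicted_class = predicted,
                  tp = as.integer(sm[4]), fp = as.integer(sm[5]),
                  p_value = as.numeric(sm[3]), is_default = is_default)
    rules[[length(rules) + 1L]] <- r
  }
  if (!length(rules)) stopf("no rules found in %s", path)
  brl_model(rules, target = target, positive = positive,
            search_kind = if (search_kind %in% c("tree", "global")) search_kind else "tree")
}

#' Write / read the JSON form of a rule model
#'
#' Lossless serialization: rules with full-precision statistics, the target
#' and positive labels, the search kind, the condition variables' level
#' sets, and any cut-point schemes.
#'
#' @param model a [brl_model].
#' @param path file path.
#' @return \code{write_rule_model_json}: invisibly, \code{path};
#'   \code{read_rule_model}: the reconstructed [brl_model].
#' @export
write_rule_model_json <- function(model, path) {
  obj <- list(
    target = model$target, positive = model$positive,
    search_kind = model$search_kind,
    levels_map = model$levels_map,
    schemes = lapply(model$schemes, function(s)
      list(variable = s$variable, thresholds = s$thresholds, labels = s$labels)),
    rules = lapply(model$rules, function(r) list(
      conditions = r$conditions, predicted_class = r$predicted_class,
      tp = r$tp, fp = r$fp, posterior = r$posterior, p_value = r$p_value,
      is_default = r$is_default)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rule_model_json
#' @export
read_rule_model <- function(path) {
  if (!grepl("\\.json$", path, ignore.case = TRUE))
    return(read_rule_model_text(path))
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(obj$rules, function(r) {
    conds <- if (length(r$conditions))
      do.call(rbind, lapply(r$conditions, function(cc)
        data.frame(variable = cc$variable, value = cc$value,
                   stringsAsFactors = FALSE)))
    else NULL
    out <- brl_rule(conds, predicted_class = r$predicted_class,
                    tp = r$tp %||% NA_integer_, fp = r$fp %||% NA_integer_,
                    p_value = r$p_value %||% NA_real_,
                    is_default = isTRUE(r$is_default))
    out
  })
  schemes <- lapply(obj$schemes, function(s)
    cut_scheme(unlist(s$thresholds), variable = s$variable))
  levels_map <- lapply(obj$levels_map, function(lv) unlist(lv))
  brl_model(rules, target = obj$target, positive = obj$positive,
            levels_map = levels_map, schemes = schemes,
            search_kind = obj$search_kind)
}
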