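#' Construct a cohort table
#'
#' A cohort table is the universal input of the package: one row per patient,
#' one column per biomarker, plus a binary diagnostic target column (e.g.
#' \code{MRDx} with levels \code{Pos}/\code{Neg}). Predictors may be continuous
#' (numeric) or categorical (character/factor). Missing values are an input
#' error: no imputation is ever performed.
#'
#' @param data a data.frame of predictors plus the target column.
#' @param target name of the target column. Must have exactly two observed
#'   levels.
#' @param positive label of the positive class. Defaults to \code{"Pos"} when
#'   present among the target levels, otherwise the first level.
#' @param spec optional variable specification, a data.frame with columns
#'   \code{name} and \code{kind} (\code{"continuous"} or \code{"categorical"})
#'   and optionally \code{units}. When given, column kinds are coerced
#'   accordingly instead of inferred.
#' @return an object of class \code{cohort_table} (a data.frame with target
#'   metadata attached).
#' @export
cohort_table <- function(data, target, positive = NULL, spec = NULL) {
  if (!is.data.frame(data)) stopf("`data` must be a data.frame")
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (nrow(data) < 1L) stopf("cohort must contain at least one record")
  if (!target %in% names(data)) stopf("target column '%s' not found", target)

  # hard error on any missing cell, naming its position
  for (col in names(data)) {
    v <- data[[col]]
    miss <- is.na(v)
    if (is.character(v)) miss <- miss | !nzchar(trimws(v))
    miss <- which(miss)
    if (length(miss)) {
      stopf("missing value in column '%s', row %d (no imputation is performed)",
            col, miss[1L])
    }
  }

  kinds <- infer_kinds(data, target, spec)
  for (col in setdiff(names(data), target)) {
    if (kinds[[col]] == "continuous") {
      v <- data[[col]]
      if (!is.numeric(v)) {
        parsed <- suppressWarnings(as.numeric(as.character(v)))
        if (anyNA(parsed)) {
          stopf("column '%s' declared continuous but row %d ('%s') is not numeric",
                col, which(is.na(parsed))[1L], as.character(v)[which(is.na(parsed))[1L]])
        }
        v <- parsed
      }
      data[[col]] <- v
    } else {
      lv <- if (!is.null(spec)) spec_levels(spec, col) else NULL
      v <- as.character(data[[col]])
      if (is.null(lv)) lv <- sort(unique(v))
      bad <- which(!v %in% lv)
      if (length(bad)) {
        stopf("column '%s', row %d: value '%s' not among declared levels (%s)",
              col, bad[1L], v[bad[1L]], paste(lv, collapse = ", "))
      }
      data[[col]] <- factor(v, levels = lv)
    }
  }

  tv <- as.character(data[[target]])
  tl <- sort(unique(tv))
  if (length(tl) != 2L) {
    stopf("target '%s' must have exactly two observed labels, found %d (%s)",
          target, length(tl), paste(tl, collapse = ", "))
  }
  if (is.null(positive)) positive <- if ("Pos" %in% tl) "Pos" else tl[1L]
  if (!positive %in% tl) stopf("positive label '%s' not among target levels", positive)
  negative <- setdiff(tl, positive)
  data[[target]] <- factor(tv, levels = c(positive, negative))

  structure(data,
            class = c("cohort_table", "data.frame"),
            target = target, positive = positive,
            kinds = kinds)
}

infer_kinds <- function(data, target, spec) {
  preds <- setdiff(names(data), target)
  kinds <- vapply(preds, function(col) {
    if (!is.null(spec)) {
      i <- match(col, spec$name)
      if (!is.na(i)) return(spec$kind[i])
    }
    v <- data[[col]]
    if (is.numeric(v)) return("continuous")
    parsed <- suppressWarnings(as.numeric(as.character(v)))
    if (!anyNA(parsed)) "continuous" else "categorical"
  }, character(1))
  as.list(kinds)
}

spec_levels <- function(spec, col) {
  if (is.null(spec$levels)) return(NULL)
  i <- match(col, spec$name)
  if (is.na(i)) return(NULL)
  lv <- spec$levels[[i]]
  if (is.null(lv) || all(is.na(lv))) NULL else lv
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d records, %d predictors, target '%s' (%s)\n",
              nrow(x), length(predictor_names(x)), target_name(x),
              paste(sprintf("%s=%d", levels(x[[target_name(x)]]),
                            tabulate(x[[target_name(x)]], 2L)), collapse = ", ")))
  invisible(x)
}

#' Accessors for cohort tables
#'
#' @param x a \code{cohort_table}.
#' @return \code{target_name}: the target column name; \code{positive_label}:
#'   the positive class label; \code{negative_label}: the other class label;
#'   \code{predictor_names}: the predictor column names; \code{variable_kind}:
#'   \code{"continuous"} or \code{"categorical"} for one predictor;
#'   \code{variable_levels}: the declared levels of a categorical predictor.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
target_name <- function(x) attr(x, "target")

#' @rdname cohort-accessors
#' @export
positive_label <- function(x) attr(x, "positive")

#' @rdname cohort-accessors
#' @export
negative_label <- function(x) setdiff(levels(x[[target_name(x)]]), positive_label(x))

#' @rdname cohort-accessors
#' @export
predictor_names <- function(x) setdiff(names(x), target_name(x))

#' @rdname cohort-accessors
#' @param variable a predictor name.
#' @export
variable_kind <- function(x, variable) {
  k <- attr(x, "kinds")[[variable]]
  if (is.null(k)) stopf("unknown variable '%s'", variable)
  k
}

#' @rdname cohort-accessors
#' @export
variable_levels <- function(x, variable) {
  if (variable_kind(x, variable) != "categorical")
    stopf("variable '%s' is continuous and has no levels", variable)
  levels(x[[variable]])
}

# row subset preserving cohort metadata (classes may become empty in folds)
cohort_rows <- function(x, idx) {
  out <- as.data.frame(x, stringsAsFactors = FALSE)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cohort_table", "data.frame"),
            target = attr(x, "target"), positive = attr(x, "positive"),
            kinds = attr(x, "kinds"))
}

# target as factor, positive level first
target_factor <- function(x) x[[target_name(x)]]

#' Read a cohort table from CSV
#'
#' Reads an RFC-4180 CSV with a header row and validates it into a
#' [cohort_table]. Variable kinds are inferred (a column whose every entry
#' parses as a number is continuous, anything else categorical) unless a
#' schema is supplied. Any empty cell is a hard error naming the row and
#' column.
#'
#' @inheritParams cohort_table
#' @param path path to the CSV file.
#' @return a \code{cohort_table}.
#' @export
read_cohort_csv <- function(path, target, positive = NULL, spec = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = character(0))
  if (!target %in% names(raw)) stopf("target column '%s' not found in %s", target, path)
  for (col in names(raw)) {
    blank <- which(!nzchar(trimws(raw[[col]])))
    if (length(blank))
      stopf("empty cell at row %d, column '%s' in %s", blank[1L], col, path)
  }
  # numeric inference on the character matrix
  for (col in names(raw)) {
    if (col == target) next
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    declared <- if (!is.null(spec)) {
      i <- match(col, spec$name); if (!is.na(i)) spec$kind[i] else NA_character_
    } else NA_character_
    if (identical(declared, "continuous") || (is.na(declared) && !anyNA(parsed))) {
      if (anyNA(parsed))
        stopf("column '%s', row %d: unparseable numeric '%s'",
              col, which(is.na(parsed))[1L], raw[[col]][which(is.na(parsed))[1L]])
      raw[[col]] <- parsed
    }
  }
  cohort_table(raw, target = target, positive = positive, spec = spec)
}

#' Write a cohort table to CSV
#'
#' @param x a \code{cohort_table}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_cohort_csv <- function(x, path) {
  out <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in names(out)) if (is.factor(out[[col]])) out[[col]] <- as.character(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Reference range tables
#'
#' A reference range table holds age- and gender-specific population means and
#' standard deviations for volumetric biomarkers, keyed by
#' (variable, gender, age band). Age bands must partition the supported age
#' range \[0, 22\] years without overlap, and every SD must be positive.
#'
#' @param entries a data.frame with columns \code{variable}, \code{gender},
#'   \code{age_min}, \code{age_max}, \code{mean}, \code{sd}.
#' @return an object of class \code{reference_range}.
#' @export
reference_range_table <- function(entries) {
  need <- c("variable", "gender", "age_min", "age_max", "mean", "sd")
  if (!all(need %in% names(entries)))
    stopf("reference table needs columns: %s", paste(need, collapse = ", "))
  if (any(entries$sd <= 0)) stopf("reference SDs must be positive")
  for (key in split(entries, list(entries$variable, entries$gender), drop = TRUE)) {
    key <- key[order(key$age_min), ]
    if (key$age_min[1L] != 0 || key$age_max[nrow(key)] != 22 ||
        (nrow(key) > 1L && any(key$age_min[-1L] != key$age_max[-nrow(key)])))
      stopf("age bands for (%s, %s) do not partition [0, 22]",
            key$variable[1L], key$gender[1L])
  }
  structure(as.data.frame(entries, stringsAsFactors = FALSE), class = c("reference_range", "data.frame"))
}

# vectorized lookup of (mean, sd) for one variable
reference_lookup <- function(ref, variable, genders, ages) {
  sub <- ref[ref$variable == variable, , drop = FALSE]
  if (!nrow(sub)) stopf("no reference entries for variable '%s'", variable)
  n <- length(ages)
  m <- numeric(n); s <- numeric(n)
  for (g in unique(as.character(genders))) {
    rows <- sub[sub$gender == g, , drop = FALSE]
    sel <- which(as.character(genders) == g)
    if (!nrow(rows))
      stopf("missing reference entry for (%s, gender %s)", variable, g)
    rows <- rows[order(rows$age_min), ]
    band <- findInterval(ages[sel], c(rows$age_min, rows$age_max[nrow(rows)]),
                         rightmost.closed = TRUE)
    if (any(band < 1L | band > nrow(rows)))
      stopf("missing reference entry for (%s, gender %s, age %s)",
            variable, g, fmt_num(ages[sel][which(band < 1L | band > nrow(rows))[1L]]))
    m[sel] <- rows$mean[band]; s[sel] <- rows$sd[band]
  }
  list(mean = m, sd = s)
}

#' Derive a low/normal/high range variable
#'
#' Categorizes a continuous biomarker against age- and gender-specific
#' reference values: values more than two reference SDs below the reference
#' mean are labelled \code{Low}, more than two SDs above \code{High}, and the
#' remainder (including values exactly at the +/-2 SD boundary) \code{Normal}.
#'
#' @param values numeric biomarker values.
#' @param ages patient ages in years (within \[0, 22\]).
#' @param genders patient genders, matching the reference table's gender codes.
#' @param ref a [reference_range_table].
#' @param variable name of the biomarker in the reference table.
#' @return a factor with levels \code{Low}, \code{Normal}, \code{High}.
#' @export
derive_range_variable <- function(values, ages, genders, ref, variable) {
  ms <- reference_lookup(ref, variable, genders, ages)
  lab <- ifelse(values < ms$mean - 2 * ms$sd, "Low",
         ifelse(values > ms$mean + 2 * ms$sd, "High", "Normal"))
  factor(lab, levels = c("Low", "Normal", "High"))
}
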