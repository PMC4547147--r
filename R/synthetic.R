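# ---- synthetic cohort roster -------------------------------------------------
# Variables mirror the standard biventricular volumetric/functional biomarkers
# reported by clinical cMRI post-processing software, plus demographics and
# binary myocardial delayed enhancement (MDE) status. Five volume variables
# additionally yield derived Low/Normal/High range columns against the
# age/gender reference table.

# derived range column -> underlying continuous variable
.range_base <- c(LVEDVR = "LVEDV", LVESVR = "LVESV", RVEDVR = "RVEDV",
                 RVESVR = "RVESV", SVR = "SV")

# base Normal(mean, sd) for continuous biomarkers without a reference table
.base_params <- list(
  LVEF  = c(60, 7),    RVEF  = c(55, 7),   SVI    = c(45, 9),
  HR    = c(100, 20),  CO    = c(4.5, 1.2), CI    = c(3.5, 0.8),
  LVEDI = c(70, 14),   LVESI = c(28, 8),   RVEDI  = c(75, 15),
  RVESI = c(34, 9),    EDD   = c(4.0, 0.8), ESD   = c(2.6, 0.6),
  ASWall = c(0.8, 0.2), PSWall = c(0.8, 0.2), FS  = c(34, 6),
  RVMajor = c(6.0, 1.0), RVMinor = c(3.0, 0.7))

#' Synthetic reference range table
#'
#' A synthetic stand-in for published age- and gender-specific control tables
#' of ventricular volumes and stroke volume (the real control tables are not
#' shipped). Means grow monotonically across the five age bands
#' \{[0,2), [2,6), [6,12), [12,18), [18,22]\} years, female means are scaled
#' to 90\% of male means, and SDs are proportional to the mean. A small
#' seeded jitter (within 2\%) varies the entries without breaking
#' monotonicity.
#'
#' @param seed RNG seed fixing the jitter.
#' @return a [reference_range_table] covering LVEDV, LVESV, RVEDV, RVESV and
#'   SV (ml).
#' @export
default_reference_table <- function(seed = 1) {
  set.seed(seed)
  bands <- data.frame(age_min = c(0, 2, 6, 12, 18), age_max = c(2, 6, 12, 18, 22))
  base <- list(LVEDV = c(30, 55, 90, 130, 150),
               LVESV = c(12, 22, 36, 52, 60),
               RVEDV = c(32, 58, 95, 137, 158),
               RVESV = c(14, 26, 43, 62, 71),
               SV    = c(18, 33, 54, 78, 90))
  relsd <- c(LVEDV = 0.15, LVESV = 0.18, RVEDV = 0.15, RVESV = 0.18, SV = 0.15)
  rows <- list()
  for (v in names(base)) for (g in c("M", "F")) {
    m <- base[[v]] * (if (g == "F") 0.9 else 1) * (1 + stats::runif(5, -0.02, 0.02))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, gender = g, age_min = bands$age_min, age_max = bands$age_max,
      mean = m, sd = relsd[[v]] * m, stringsAsFactors = FALSE)
  }
  reference_range_table(do.call(rbind, rows))
}

#' Default class effects of the synthetic generator
#'
#' Shifts (in SD units) applied to the positive class's continuous
#' biomarkers: positives have dilated ventricular volumes, depressed
#' ejection fractions and fractional shortening, and a mildly elevated
#' stroke volume index. Together with the class-conditional MDE rates these
#' effects carry the recoverable signal.
#'
#' @return named numeric vector of SD-unit shifts.
#' @export
default_effect_map <- function() {
  c(LVEDV = 1.0, LVESV = 1.2, RVESV = 0.8,
    RVEF = -1.0, LVEF = -1.0, FS = -0.8, SVI = 0.5)
}

#' Synthetic cohort configuration
#'
#' Generative parameters for [generate_cohort]. Defaults emulate the
#' composition of an 83-patient pediatric cardiomyopathy cohort: 32
#' positives and 51 negatives, MDE present in 17/32 positives and 1/51
#' negatives, male fractions 20/32 and 31/51, ages uniform on \[0, 22\]
#' years.
#'
#' @param n_pos,n_neg class sizes (exact, not sampled).
#' @param seed RNG seed; the cohort is a deterministic function of the
#'   configuration.
#' @param mde_rate_pos,mde_rate_neg class-conditional P(MDE = Yes).
#' @param male_rate_pos,male_rate_neg class-conditional P(Gender = M).
#' @param effect_map named SD-unit shifts for positives
#'   ([default_effect_map]); an empty vector gives a null cohort with
#'   identical class-conditional continuous distributions.
#' @param reference a [reference_range_table] for the volume variables.
#' @param implanted internal; set via [implant_rule_model].
#' @return an object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_pos = 32, n_neg = 51, seed = 1,
                             mde_rate_pos = 17 / 32, mde_rate_neg = 1 / 51,
                             male_rate_pos = 20 / 32, male_rate_neg = 31 / 51,
                             effect_map = default_effect_map(),
                             reference = default_reference_table(),
                             implanted = NULL) {
  rates <- c(mde_rate_pos, mde_rate_neg, male_rate_pos, male_rate_neg)
  if (any(rates < 0 | rates > 1)) stopf("rates must lie in [0, 1]")
  if (n_pos < 0 || n_neg < 0) stopf("class sizes must be non-negative")
  structure(list(n_pos = n_pos, n_neg = n_neg, seed = seed,
                 mde_rate_pos = mde_rate_pos, mde_rate_neg = mde_rate_neg,
                 male_rate_pos = male_rate_pos, male_rate_neg = male_rate_neg,
                 effect_map = effect_map, reference = reference,
                 implanted = implanted),
            class = "synthetic_config")
}

# truncated normal via inverse-CDF; bounds may be +/-Inf
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  plo <- pmin(pmax(plo, 0), 1 - 1e-12); phi <- pmax(pmin(phi, 1), plo + 1e-12)
  u <- stats::runif(n, plo, phi)
  v <- stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), mean, sd)
  lo <- rep_len(lo, n); hi <- rep_len(hi, n)
  fin <- is.finite(lo)
  v[fin] <- pmax(v[fin], lo[fin] + 1e-9 * pmax(1, abs(lo[fin])))
  fin <- is.finite(hi)
  v[fin] <- pmin(v[fin], hi[fin])
  v
}

# largest-remainder allocation of n into counts proportional to weights
# (deterministic; exact when n * weights are integers)
largest_remainder <- function(n, weights) {
  raw <- n * weights
  base <- floor(raw + 1e-9)
  left <- n - sum(base)
  if (left > 0) {
    frac <- raw - base
    take <- order(-frac, seq_along(frac))[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# interval bounds (lo, hi] of a condition value under a cut scheme
scheme_bounds <- function(scheme, value) {
  i <- match(value, scheme$labels)
  if (is.na(i)) stopf("'%s' is not an interval of the scheme for '%s'",
                      value, scheme$variable)
  thr <- c(-Inf, scheme$thresholds, Inf)
  c(lo = thr[i], hi = thr[i + 1L])
}

#' Implant a rule mechanism into a synthetic configuration
#'
#' Turns a rule model into a generative mechanism: each rule's condition
#' region receives, per class, a share of records equal to its scaled
#' (TP, FP) coverage, so generated cohorts reproduce the model's coverage
#' counts (exactly when the scaled counts are integral, and converging as n
#' grows otherwise). Rules covering no records (TP = FP = 0, posterior 0.5)
#' stay neutral and receive no mass; any residual class mass is generated
#' outside all rule regions.
#'
#' @param cfg a [synthetic_config]; its current \code{n_pos}/\code{n_neg}
#'   define the totals the rule counts are scaled against.
#' @param model a [brl_model] with annotated rules, or a list of
#'   [brl_rule]s. Condition variables must belong to the synthetic roster;
#'   conditions on continuous variables require the model to carry a
#'   cut-point scheme.
#' @return the configuration with the mechanism installed; class sizes may
#'   be scaled afterwards without changing the region shares.
#' @export
implant_rule_model <- function(cfg, model) {
  rules <- if (inherits(model, "brl_model")) model$rules else model
  schemes <- if (inherits(model, "brl_model")) model$schemes else list()
  rules <- Filter(function(r) !r$is_default && (r$tp + r$fp) > 0, rules)
  if (!length(rules)) return(cfg)
  if (any(vapply(rules, function(r) is.na(r$tp) || is.na(r$fp), logical(1))))
    stopf("implanted rules must carry coverage counts; annotate the model first")
  pos_cnt <- vapply(rules, function(r)
    if (r$predicted_class == "Pos") r$tp else r$fp, numeric(1))
  neg_cnt <- vapply(rules, function(r)
    if (r$predicted_class == "Pos") r$fp else r$tp, numeric(1))
  w_pos <- pos_cnt / cfg$n_pos; w_neg <- neg_cnt / cfg$n_neg
  if (sum(w_pos) > 1 + 1e-9 || sum(w_neg) > 1 + 1e-9)
    stopf("rule coverages exceed the configured class sizes")
  # validate conditions against the roster and resolve continuous bounds
  for (r in rules) for (i in seq_len(nrow(r$conditions))) {
    v <- r$conditions$variable[i]
    if (v %in% c("MDE", "Gender") || v %in% names(.range_base)) next
    if (v %in% c(names(.base_params), unname(.range_base))) {
      if (is.null(schemes[[v]]))
        stopf("condition on continuous '%s' needs a cut-point scheme", v)
      scheme_bounds(schemes[[v]], r$conditions$value[i])  # errors if label unknown
    } else stopf("condition variable '%s' is not in the synthetic roster", v)
  }
  cfg$implanted <- list(rules = rules, schemes = schemes,
                        w_pos = w_pos, w_neg = w_neg)
  cfg
}

#' Generate a synthetic cohort
#'
#' Draws exactly \code{n_pos} positive and \code{n_neg} negative records.
#' Gender and MDE are sampled class-conditionally; ages are uniform on
#' \[0, 22\]; the five reference volumes are drawn from the age/gender
#' reference Normal shifted by \code{effect_map} SD units for positives, the
#' remaining continuous biomarkers from fixed base Normals shifted likewise.
#' The five derived range columns (LVEDVR, LVESVR, RVEDVR, RVESVR, SVR) are
#' then computed with [derive_range_variable]. With an implanted rule
#' mechanism, records are first allotted to rule regions (largest-remainder
#' allocation of the scaled coverages) and conditioned variables drawn from
#' the matching truncated distributions; leftover records are rejection
#' sampled outside every rule region. Deterministic given the
#' configuration.
#'
#' @param cfg a [synthetic_config].
#' @return a [cohort_table] with target \code{MRDx} (levels Pos/Neg) and 30
#'   predictors.
#' @export
generate_cohort <- function(cfg) {
  set.seed(cfg$seed)
  ref_vars <- unname(.range_base)

  draw_base <- function(n, cl) {
    male_rate <- if (cl == "Pos") cfg$male_rate_pos else cfg$male_rate_neg
    mde_rate <- if (cl == "Pos") cfg$mde_rate_pos else cfg$mde_rate_neg
    d <- data.frame(
      Gender = ifelse(stats::runif(n) < male_rate, "M", "F"),
      Age = stats::runif(n, 0, 22),
      MDE = ifelse(stats::runif(n) < mde_rate, "Yes", "No"),
      stringsAsFactors = FALSE)
    for (v in ref_vars) {
      ms <- reference_lookup(cfg$reference, v, d$Gender, d$Age)
      shift <- if (cl == "Pos") (cfg$effect_map[v] %|NA|% 0) else 0
      d[[v]] <- stats::rnorm(n, ms$mean + shift * ms$sd, ms$sd)
    }
    for (v in names(.base_params)) {
      p <- .base_params[[v]]
      shift <- if (cl == "Pos") (cfg$effect_map[v] %|NA|% 0) else 0
      d[[v]] <- stats::rnorm(n, p[1] + shift * p[2], p[2])
    }
    d
  }

  # overwrite the conditioned variables of rows `rows` so they satisfy `rule`
  force_rule <- function(d, rows, rule, cl) {
    n <- length(rows)
    if (!n) return(d)
    for (i in seq_len(nrow(rule$conditions))) {
      v <- rule$conditions$variable[i]; val <- rule$conditions$value[i]
      if (v %in% c("MDE", "Gender")) {
        d[[v]][rows] <- val
      } else if (v %in% names(.range_base)) {
        u <- .range_base[[v]]
        ms <- reference_lookup(cfg$reference, u, d$Gender[rows], d$Age[rows])
        lo <- switch(val, Low = -Inf, Normal = ms$mean - 2 * ms$sd,
                     High = ms$mean + 2 * ms$sd,
                     stopf("unknown range label '%s'", val))
        hi <- switch(val, Low = ms$mean - 2 * ms$sd - 1e-9,
                     Normal = ms$mean + 2 * ms$sd, High = Inf)
        shift <- if (cl == "Pos") (cfg$effect_map[u] %|NA|% 0) else 0
        d[[u]][rows] <- rtnorm(n, ms$mean + shift * ms$sd, ms$sd, lo, hi)
      } else {
        b <- scheme_bounds(cfg$implanted$schemes[[v]], val)
        p <- if (v %in% names(.base_params)) .base_params[[v]] else {
          ms <- reference_lookup(cfg$reference, v, d$Gender[rows], d$Age[rows])
          NULL
        }
        shift <- if (cl == "Pos") (cfg$effect_map[v] %|NA|% 0) else 0
        if (is.null(p)) {
          d[[v]][rows] <- rtnorm(n, ms$mean + shift * ms$sd, ms$sd, b["lo"], b["hi"])
        } else {
          d[[v]][rows] <- rtnorm(n, p[1] + shift * p[2], p[2], b["lo"], b["hi"])
        }
      }
    }
    d
  }

  # does row set satisfy a rule, given raw columns (ranges derived on the fly)
  matches_rule <- function(d, rule) {
    hit <- rep(TRUE, nrow(d))
    for (i in seq_len(nrow(rule$conditions))) {
      v <- rule$conditions$variable[i]; val <- rule$conditions$value[i]
      col <- if (v %in% names(.range_base)) {
        u <- .range_base[[v]]
        as.character(derive_range_variable(d[[u]], d$Age, d$Gender, cfg$reference, u))
      } else if (v %in% c("MDE", "Gender")) d[[v]]
      else as.character(apply_scheme(d[[v]], cfg$implanted$schemes[[v]]))
      hit <- hit & (col == val)
    }
    hit
  }

  gen_class <- function(cl, n) {
    if (n == 0L) return(NULL)
    d <- draw_base(n, cl)
    if (!is.null(cfg$implanted)) {
      w <- if (cl == "Pos") cfg$implanted$w_pos else cfg$implanted$w_neg
      alloc <- largest_remainder(n, c(w, max(0, 1 - sum(w))))
      ends <- cumsum(alloc)
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      for (r in seq_along(cfg$implanted$rules)) {
        if (alloc[r] == 0L) next
        d <- force_rule(d, starts[r]:ends[r], cfg$implanted$rules[[r]], cl)
      }
      # remainder: resample until outside every rule region
      rem <- if (alloc[length(alloc)] > 0L)
        starts[length(alloc)]:ends[length(alloc)] else integer(0)
      tries <- 0L
      while (length(rem)) {
        inside <- rep(FALSE, nrow(d))
        for (rule in cfg$implanted$rules)
          inside <- inside | matches_rule(d, rule)
        bad <- intersect(rem, which(inside))
        if (!length(bad)) break
        tries <- tries + 1L
        if (tries > 1000L)
          stopf("could not sample records outside the implanted rule regions")
        d[bad, ] <- draw_base(length(bad), cl)
      }
    }
    d$MRDx <- cl
    d
  }

  d <- rbind(gen_class("Pos", cfg$n_pos), gen_class("Neg", cfg$n_neg))
  for (rng in names(.range_base)) {
    u <- .range_base[[rng]]
    d[[rng]] <- as.character(derive_range_variable(d[[u]], d$Age, d$Gender,
                                                   cfg$reference, u))
  }
  d <- d[sample.int(nrow(d)), , drop = FALSE]
  rownames(d) <- NULL
  spec <- data.frame(name = setdiff(names(d), "MRDx"), kind = "continuous",
                     stringsAsFactors = FALSE)
  spec$kind[spec$name %in% c("Gender", "MDE", names(.range_base))] <- "categorical"
  spec$levels <- lapply(spec$name, function(v) {
    if (v == "Gender") c("F", "M")
    else if (v == "MDE") c("No", "Yes")
    else if (v %in% names(.range_base)) c("Low", "Normal", "High")
    else NULL
  })
  cohort_table(d, target = "MRDx", positive = "Pos", spec = spec)
}

`%|NA|%` <- function(a, b) if (length(a) != 1L || is.na(a)) b else a
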