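# Reproductive scoring rules: assay censoring, LH surge classification,
# estrous-cycle metrics and summary-statistic effect sizes.

#' Study scoring constants
#'
#' Reads the versioned YAML of scoring constants shipped with the package:
#' the LH surge rule (3.8 ng/ml, mean + 3 SD of proestrus-morning values,
#' strict comparison) and the assay reportable ranges.
#'
#' @param path Path to a constants YAML; defaults to the packaged file.
#' @return A named list (`version`, `lh_surge`, `assay_ranges`).
#' @export
#' @examples
#' study_constants()$lh_surge$threshold_ng_ml
study_constants <- function(path = system.file("extdata",
                                               "assay_constants.yaml",
                                               package = "pscpipe")) {
  yaml::read_yaml(path)
}

#' Assay reportable ranges
#'
#' Constructor for an assay's reportable range; concentrations outside it
#' are censored to the bounds. Built-in defaults: ultrasensitive LH
#' 0.16-40 ng/ml (at the study's 1:10 dilution) and corticosterone EIA
#' 3.9-1,000 ng/ml.
#'
#' @param analyte `"LH"` or `"corticosterone"` (free-form labels allowed
#'   when both bounds are given).
#' @param lower,upper Range bounds (ng/ml, lower < upper); defaults come
#'   from the built-in table for known analytes.
#' @return An object of class `assay_range`.
#' @export
#' @examples
#' assay_range("LH")
#' assay_range("corticosterone")
assay_range <- function(analyte, lower = NULL, upper = NULL) {
  defaults <- list(
    LH = c(0.16, 40),
    corticosterone = c(3.9, 1000)
  )
  if (is.null(lower) || is.null(upper)) {
    if (!analyte %in% names(defaults)) {
      stop("no built-in range for analyte `", analyte,
           "`; give `lower` and `upper`", call. = FALSE)
    }
    bounds <- defaults[[analyte]]
    lower <- if (is.null(lower)) bounds[1] else lower
    upper <- if (is.null(upper)) bounds[2] else upper
  }
  check_scalar(lower, "lower")
  check_scalar(upper, "upper")
  if (lower >= upper) {
    stop("`lower` must be below `upper`", call. = FALSE)
  }
  structure(list(analyte = analyte, lower = lower, upper = upper),
            class = "assay_range")
}

#' Censor concentrations to an assay's reportable range
#'
#' Clips values to `[lower, upper]` and flags clipped entries. Idempotent:
#' censoring twice equals censoring once.
#'
#' @param values Numeric concentrations (ng/ml).
#' @param range An [assay_range()].
#' @return A list with `values` (clipped) and `censored` (logical flags).
#' @export
#' @examples
#' censor_to_range(c(55, 0.05, 5), assay_range("LH"))
censor_to_range <- function(values, range) {
  stopifnot(inherits(range, "assay_range"))
  if (!is.numeric(values)) {
    stop("`values` must be numeric", call. = FALSE)
  }
  clipped <- pmin(pmax(values, range$lower), range$upper)
  list(values = clipped, censored = clipped != values & !is.na(values))
}

#' LH surge classification rule
#'
#' The study constant: an animal exhibits an LH surge if any PM value
#' strictly exceeds 3.8 ng/ml, a threshold derived as mean + 3 SD of the
#' proestrus-morning (0 h) LH concentrations. The default rule stores that
#' constant; [surge_threshold()] recomputes it from supplied AM data.
#'
#' @param threshold Threshold in ng/ml (> 0; default 3.8).
#' @param sd_multiplier SD multiplier used when deriving a threshold from
#'   AM values (default 3).
#' @param strict Use strict `>` comparison (default `TRUE`; boundary
#'   equality is not a surge).
#' @return An object of class `surge_rule`.
#' @export
surge_rule <- function(threshold = 3.8, sd_multiplier = 3, strict = TRUE) {
  check_scalar(threshold, "threshold", positive = TRUE)
  check_scalar(sd_multiplier, "sd_multiplier", nonnegative = TRUE)
  structure(
    list(threshold = threshold, sd_multiplier = sd_multiplier,
         strict = isTRUE(strict)),
    class = "surge_rule"
  )
}

#' Surge threshold from morning LH values
#'
#' Mean plus `sd_multiplier` sample standard deviations of the AM
#' (proestrus morning, 0 h) LH concentrations.
#'
#' @param am_values At least two AM LH concentrations (ng/ml).
#' @param sd_multiplier SD multiplier (default 3).
#' @return Threshold in ng/ml.
#' @export
#' @examples
#' surge_threshold(c(0.3, 0.8, 1.3))
surge_threshold <- function(am_values, sd_multiplier = 3) {
  if (!is.numeric(am_values) || length(am_values) < 2L) {
    stop("need at least two AM values", call. = FALSE)
  }
  mean(am_values) + sd_multiplier * stats::sd(am_values)
}

#' Classify an LH surge
#'
#' An animal surged if any PM LH value exceeds the rule threshold
#' (strictly, under the default rule). Values censored at the assay
#' maximum (40 ng/ml) exceed any threshold below 40 and therefore count.
#'
#' @param series A hormone series data frame with columns `period`
#'   (`"AM"`/`"PM"`) and `conc_ng_ml` (as from [generate_lh_profiles()]),
#'   or a numeric vector of PM values.
#' @param rule A [surge_rule()].
#' @return A list with `surged` (logical) and `max_pm` (ng/ml).
#' @export
#' @examples
#' classify_surge(c(0.5, 4.0))
#' classify_surge(c(3.8))  # boundary is not a surge
classify_surge <- function(series, rule = surge_rule()) {
  stopifnot(inherits(rule, "surge_rule"))
  pm <- if (is.numeric(series)) {
    series
  } else {
    stopifnot(is.data.frame(series),
              all(c("period", "conc_ng_ml") %in% names(series)))
    series$conc_ng_ml[series$period == "PM"]
  }
  if (length(pm) == 0L) {
    stop("no PM samples present", call. = FALSE)
  }
  mx <- max(pm)
  surged <- if (rule$strict) mx > rule$threshold else mx >= rule$threshold
  list(surged = surged, max_pm = mx)
}

#' Mean diestrous PM LH
#'
#' Average of the two designated PM LH samples of a diestrous animal (end
#' of the adult paradigm and lights out).
#'
#' @param series A hormone series data frame (columns `period`,
#'   `conc_ng_ml`) whose PM rows are the two designated samples, or a
#'   numeric vector of length two.
#' @return Mean concentration in ng/ml.
#' @export
#' @examples
#' mean_diestrus_lh(c(0.4, 0.6))
mean_diestrus_lh <- function(series) {
  pm <- if (is.numeric(series)) {
    series
  } else {
    stopifnot(is.data.frame(series),
              all(c("period", "conc_ng_ml") %in% names(series)))
    series$conc_ng_ml[series$period == "PM"]
  }
  if (length(pm) != 2L || anyNA(pm)) {
    stop("both designated PM samples must be present", call. = FALSE)
  }
  mean(pm)
}

#' Estrous-cycle metrics
#'
#' From a daily stage sequence over diestrus (`"D"`), proestrus (`"P"`)
#' and estrus (`"E"`): the number of cycles (days in proestrus preceded by
#' diestrus or estrus), the mean cycle length (days between the first days
#' of successive proestrous runs; `NA` with fewer than two runs), and the
#' percentage of days in each stage.
#'
#' @param stages Character vector of daily stages (length >= 2, typically
#'   a 21 d monitoring window).
#' @return A list of class `cycle_metrics` with `n_cycles`,
#'   `mean_cycle_length_d` and `pct_days` (named percentages summing to
#'   100).
#' @export
#' @examples
#' cycle_metrics(c(rep(c("D", "D", "P", "E"), 5), "D"))
cycle_metrics <- function(stages) {
  stages <- as.character(stages)
  if (length(stages) < 2L) {
    stop("need at least two days of staging", call. = FALSE)
  }
  if (!all(stages %in% c("D", "P", "E"))) {
    stop("stages may only contain D, P, E", call. = FALSE)
  }
  n <- length(stages)
  prev <- stages[-n]
  curr <- stages[-1]
  n_cycles <- sum(curr == "P" & prev %in% c("D", "E"))
  # first days of each proestrous run
  p_starts <- which(stages == "P" & c(TRUE, stages[-n] != "P"))
  mean_len <- if (length(p_starts) >= 2L) {
    mean(diff(p_starts))
  } else {
    NA_real_
  }
  pct <- 100 * vapply(c(D = "D", P = "P", E = "E"),
                      function(s) mean(stages == s), numeric(1))
  structure(
    list(n_cycles = n_cycles, mean_cycle_length_d = mean_len,
         pct_days = pct),
    class = "cycle_metrics"
  )
}

#' @export
print.cycle_metrics <- function(x, ...) {
  cat(sprintf(
    "<cycle_metrics> %d cycles, mean length %s d; %%days D/P/E = %s\n",
    x$n_cycles, formatC(x$mean_cycle_length_d, digits = 3, format = "fg"),
    paste(sprintf("%.1f", x$pct_days), collapse = "/")
  ))
  invisible(x)
}

#' Two-sample t statistic from printed summaries
#'
#' Welch-style reconstruction of a two-sample t statistic from group
#' means and SEMs as printed in a results section:
#' `t = (mean1 - mean2) / sqrt(sem1^2 + sem2^2)` with
#' `df = n1 + n2 - 2`.
#'
#' @param mean1,mean2 Group means.
#' @param sem1,sem2 Group standard errors of the mean (> 0).
#' @param n1,n2 Group sizes (>= 2).
#' @return A list with `t` and `df`.
#' @export
#' @examples
#' two_sample_t_from_summary(2.8, 0.06, 25, 2.9, 0.06, 24)
two_sample_t_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  check_summary_inputs(sem1, n1, sem2, n2)
  list(
    t = (mean1 - mean2) / sqrt(sem1^2 + sem2^2),
    df = n1 + n2 - 2
  )
}

#' Cohen's d from printed summaries
#'
#' Standardized mean difference reconstructed from printed means, SEMs and
#' group sizes: SDs are recovered as `sem * sqrt(n)` and pooled with
#' `n - 1` weights.
#'
#' @inheritParams two_sample_t_from_summary
#' @return Cohen's d.
#' @export
#' @examples
#' cohens_d_from_summary(2.8, 0.06, 25, 2.9, 0.06, 24)
cohens_d_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  check_summary_inputs(sem1, n1, sem2, n2)
  sd1 <- sem1 * sqrt(n1)
  sd2 <- sem2 * sqrt(n2)
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (mean1 - mean2) / pooled
}

check_summary_inputs <- function(sem1, n1, sem2, n2) {
  check_scalar(sem1, "sem1", positive = TRUE)
  check_scalar(sem2, "sem2", positive = TRUE)
  check_scalar(n1, "n1", integerish = TRUE)
  check_scalar(n2, "n2", integerish = TRUE)
  if (n1 < 2 || n2 < 2) {
    stop("group sizes must be at least 2", call. = FALSE)
  }
  invisible(TRUE)
}

#' Contrast t-ratio
#'
#' The t-ratio of a model contrast from its printed estimate and standard
#' error, `t = estimate / se`, as tabulated for pairwise post hoc
#' comparisons.
#'
#' @param estimate Contrast estimate.
#' @param se Standard error (> 0).
#' @return The t-ratio.
#' @export
#' @examples
#' contrast_t(-71.38, 2.981)
contrast_t <- function(estimate, se) {
  check_scalar(estimate, "estimate")
  check_scalar(se, "se", positive = TRUE)
  estimate / se
}
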