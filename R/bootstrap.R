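# Design-aware percentile bootstrap of group means and differences.

#' Bootstrap specification
#'
#' Parameters of the percentile bootstrap used to put confidence intervals
#' on group means and on differences in means: 5,000 resampling iterations
#' and the 2.5th/97.5th percentiles of the recorded values as interval
#' bounds. The resampling unit accounts for the experimental design:
#' events within a cell are dependent, so the default resamples whole
#' cells with replacement within each group and pools their events;
#' `"mouse"` and plain `"event"` resampling are available alternatives.
#'
#' @param n_iterations Number of bootstrap iterations (>= 1; default 5000).
#' @param lower_percentile,upper_percentile Interval percentiles
#'   (0 < lower < upper < 100).
#' @param resample_unit `"cell"`, `"mouse"` or `"event"`.
#' @param seed Integer seed.
#' @return An object of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(n_iterations = 5000, lower_percentile = 2.5,
                           upper_percentile = 97.5,
                           resample_unit = c("cell", "mouse", "event"),
                           seed = 1L) {
  check_scalar(n_iterations, "n_iterations", positive = TRUE,
               integerish = TRUE)
  check_scalar(lower_percentile, "lower_percentile", positive = TRUE)
  check_scalar(upper_percentile, "upper_percentile", positive = TRUE)
  if (!(lower_percentile < upper_percentile && upper_percentile < 100)) {
    stop("need 0 < lower_percentile < upper_percentile < 100",
         call. = FALSE)
  }
  structure(
    list(
      n_iterations = as.integer(n_iterations),
      lower_percentile = lower_percentile,
      upper_percentile = upper_percentile,
      resample_unit = match.arg(resample_unit),
      seed = as.integer(seed)
    ),
    class = "bootstrap_spec"
  )
}

#' Hierarchical percentile bootstrap of group means
#'
#' For each iteration, resamples units (cells, mice or single events) with
#' replacement within each group, pools the sampled units' events and
#' records the group mean of `statistic`; differences in means are recorded
#' for each requested pair. Point estimates are the averages of the
#' recorded values over iterations and confidence intervals are the
#' `lower_percentile`/`upper_percentile` empirical quantiles (linear
#' interpolation of the sorted bootstrap values). With `resample_unit =
#' "event"` (or one event per unit) this reduces to the ordinary
#' nonparametric bootstrap.
#'
#' @param data A data frame of per-event records.
#' @param value Column name of the event value.
#' @param group Column name of the group label.
#' @param unit Column name of the resampling unit id (e.g. cell id);
#'   ignored when `spec$resample_unit == "event"`.
#' @param spec A [bootstrap_spec()].
#' @param pairs List of length-2 character vectors of group labels to
#'   difference (first minus second); defaults to all groups' pairwise
#'   combinations when `NULL` and the canonical four for the full design.
#' @param statistic Function reducing a numeric vector to a scalar
#'   (default `mean`).
#' @return A list of class `hier_bootstrap` with elements `groups` (data
#'   frame: `group`, `estimate`, `ci_low`, `ci_high`), `pairs` (data
#'   frame: `pair`, `estimate`, `ci_low`, `ci_high`) and the echoed
#'   `spec`.
#' @export
#' @examples
#' df <- data.frame(value = rnorm(60), group = rep(c("A", "B"), each = 30),
#'                  cell = rep(1:20, each = 3))
#' hierarchical_bootstrap(df, unit = "cell",
#'                        spec = bootstrap_spec(n_iterations = 200),
#'                        pairs = list(c("A", "B")))
hierarchical_bootstrap <- function(data, value = "value", group = "group",
                                   unit = "cell",
                                   spec = bootstrap_spec(),
                                   pairs = NULL, statistic = mean) {
  stopifnot(is.data.frame(data), inherits(spec, "bootstrap_spec"))
  gl <- as.character(data[[group]])
  labels <- unique(gl)
  if (is.null(pairs)) {
    if (setequal(labels, psc_groups())) {
      pairs <- psc_posthoc_pairs()
    } else {
      pairs <- utils::combn(labels, 2, simplify = FALSE)
    }
  }
  for (pr in pairs) {
    if (!all(pr %in% labels)) {
      stop("pair labels must be present in the data", call. = FALSE)
    }
  }
  vals <- as.numeric(data[[value]])
  # per group: list of per-unit value vectors
  unit_values <- lapply(labels, function(g) {
    v <- vals[gl == g]
    if (spec$resample_unit == "event") {
      as.list(v)
    } else {
      u <- as.character(data[[unit]][gl == g])
      unname(split(v, u))
    }
  })
  names(unit_values) <- labels
  if (any(vapply(unit_values, length, integer(1)) == 0L)) {
    stop("every group needs at least one resampleable unit", call. = FALSE)
  }

  b <- spec$n_iterations
  means <- matrix(NA_real_, nrow = b, ncol = length(labels),
                  dimnames = list(NULL, labels))
  with_seed(spec$seed, {
    for (g in seq_along(labels)) {
      uv <- unit_values[[g]]
      n_units <- length(uv)
      single <- all(lengths(uv) == 1L)
      if (single) {
        # fast path: units are single events
        v <- unlist(uv, use.names = FALSE)
        draw <- matrix(v[sample.int(n_units, n_units * b, replace = TRUE)],
                       nrow = n_units)
        means[, g] <- if (identical(statistic, mean)) {
          colMeans(draw)
        } else {
          apply(draw, 2, statistic)
        }
      } else {
        for (it in seq_len(b)) {
          idx <- sample.int(n_units, n_units, replace = TRUE)
          means[it, g] <- statistic(unlist(uv[idx], use.names = FALSE))
        }
      }
    }
  })

  probs <- c(spec$lower_percentile, spec$upper_percentile) / 100
  group_ci <- t(apply(means, 2, stats::quantile, probs = probs,
                      names = FALSE))
  groups_df <- data.frame(
    group = labels,
    estimate = colMeans(means),
    ci_low = group_ci[, 1],
    ci_high = group_ci[, 2],
    row.names = NULL
  )
  pairs_df <- do.call(rbind, lapply(pairs, function(pr) {
    d <- means[, pr[1]] - means[, pr[2]]
    ci <- stats::quantile(d, probs = probs, names = FALSE)
    data.frame(
      pair = paste(pr, collapse = " - "),
      estimate = mean(d),
      ci_low = ci[1],
      ci_high = ci[2]
    )
  }))
  structure(
    list(groups = groups_df, pairs = pairs_df, spec = spec),
    class = "hier_bootstrap"
  )
}

#' @export
print.hier_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<hier_bootstrap> %d iterations, unit = %s, %g%%/%g%% percentiles\n",
    x$spec$n_iterations, x$spec$resample_unit,
    x$spec$lower_percentile, x$spec$upper_percentile
  ))
  cat("Group means:\n")
  print(x$groups, digits = 4)
  cat("Differences in means:\n")
  print(x$pairs, digits = 4)
  invisible(x)
}

#' Full group-distribution comparison
#'
#' The complete comparison stage for one event property (interevent
#' interval or amplitude): the omnibus k-sample Anderson-Darling test over
#' all groups, the four prespecified Holm-adjusted post hoc pairs, and the
#' hierarchical percentile bootstrap of group means and differences.
#'
#' @inheritParams hierarchical_bootstrap
#' @inheritParams pairwise_ad_posthoc
#' @param boot_spec A [bootstrap_spec()].
#' @param method p-value method for the AD tests.
#' @return A list of class `group_comparison` with `omnibus` (the
#'   [ad_ksample()] result), `posthoc` (pairwise table) and `bootstrap`
#'   (the [hierarchical_bootstrap()] result).
#' @export
compare_groups <- function(data, value = "value", group = "group",
                           unit = "cell", pairs = NULL,
                           boot_spec = bootstrap_spec(),
                           method = c("asymptotic", "permutation"),
                           n_permutations = 9999) {
  method <- match.arg(method)
  labels <- unique(as.character(data[[group]]))
  if (is.null(pairs)) {
    pairs <- if (setequal(labels, psc_groups())) {
      psc_posthoc_pairs()
    } else {
      utils::combn(labels, 2, simplify = FALSE)
    }
  }
  omnibus <- ad_ksample(data, value = value, group = group, method = method,
                        n_permutations = n_permutations,
                        seed = derive_seed(boot_spec$seed, 11L))
  posthoc <- pairwise_ad_posthoc(data, value = value, group = group,
                                 pairs = pairs, method = method,
                                 n_permutations = n_permutations,
                                 seed = derive_seed(boot_spec$seed, 13L))
  boot <- hierarchical_bootstrap(data, value = value, group = group,
                                 unit = unit, spec = boot_spec,
                                 pairs = pairs)
  structure(
    list(omnibus = omnibus, posthoc = posthoc, bootstrap = boot),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Omnibus: ")
  cat(sprintf("A2akN = %.4f, standardized = %.3f, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$standardized,
              x$omnibus$p.value))
  cat("Post hoc pairs (Holm-adjusted):\n")
  print(x$posthoc, digits = 4)
  print(x$bootstrap)
  invisible(x)
}

#' Tidy export of a group comparison
#'
#' @param comparison A `group_comparison` from [compare_groups()].
#' @param path Optional CSV path; written when supplied.
#' @return A data frame with one row per post hoc pair: `pair`,
#'   `statistic`, `p_raw`, `p_holm`, `mean_diff`, `ci_low`, `ci_high`.
#' @export
comparison_table <- function(comparison, path = NULL) {
  stopifnot(inherits(comparison, "group_comparison"))
  ph <- comparison$posthoc
  bt <- comparison$bootstrap$pairs
  out <- data.frame(
    pair = ph$pair,
    statistic = ph$statistic,
    p_raw = ph$p_raw,
    p_holm = ph$p_holm,
    mean_diff = bt$estimate,
    ci_low = bt$ci_low,
    ci_high = bt$ci_high
  )
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
  }
  out
}
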