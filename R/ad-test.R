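# k-sample Anderson-Darling test with midrank tie handling, asymptotic
# p-values by tabulated interpolation and a permutation fallback.

# Core statistic. Returns the midrank-version criterion A2akN, the
# standardization SD sigma_N and the standardized statistic
# t = (A2 - (k-1)) / sigma_N, whose null distribution is tabulated.
ad_ksample_stat <- function(groups) {
  k <- length(groups)
  ns <- lengths(groups)
  pool <- unlist(groups, use.names = FALSE)
  n_total <- length(pool)
  z <- sort(unique(pool))
  n_distinct <- length(z)
  if (n_distinct < 2L) {
    stop("pooled sample must contain at least two distinct values",
         call. = FALSE)
  }
  l <- as.numeric(tabulate(match(pool, z), n_distinct))
  b_j <- cumsum(l) - l / 2
  denom <- b_j * (n_total - b_j) - n_total * l / 4
  ok <- denom > 0
  a2 <- 0
  for (i in seq_len(k)) {
    f_i <- as.numeric(tabulate(match(groups[[i]], z), n_distinct))
    m_ij <- cumsum(f_i) - f_i / 2
    term <- (l / n_total) * (n_total * m_ij - ns[i] * b_j)^2 / denom
    a2 <- a2 + sum(term[ok]) / ns[i]
  }
  a2 <- a2 * (n_total - 1) / n_total

  # Null variance of A2akN (exact under the continuous-population null).
  big_h <- sum(1 / ns)
  hh <- cumsum(1 / seq_len(n_total - 1L))
  h <- hh[n_total - 1L]
  i_idx <- seq_len(n_total - 2L)
  g <- sum((h - hh[i_idx]) / (n_total - i_idx))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * big_h
  b <- (2 * g - 4) * k^2 + 8 * h * k +
    (2 * g - 14 * h - 4) * big_h - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k +
    (2 * h - 6) * big_h + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  sigma_sq <- (a * n_total^3 + b * n_total^2 + cc * n_total + d) /
    ((n_total - 1) * (n_total - 2) * (n_total - 3))
  sigma <- sqrt(sigma_sq)
  list(A2 = a2, sigma = sigma, t = (a2 - (k - 1)) / sigma)
}

# Asymptotic p-value for the standardized statistic, by interpolation of
# the tabulated null quantiles of the criterion for m = k - 1. Quantiles
# are parameterized as t_m(alpha) = b0 + b1/sqrt(m) + b2/m at seven alpha
# levels; log(alpha) is interpolated in t with a natural spline (linear
# extrapolation outside the tabulated 0.001-0.25 range).
ad_pvalue_asymptotic <- function(t, k) {
  m <- k - 1
  alpha <- c(0.25, 0.10, 0.05, 0.025, 0.01, 0.005, 0.001)
  b0 <- c(0.675, 1.281, 1.645, 1.960, 2.326, 2.573, 3.085)
  b1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822, 2.364, 3.615)
  b2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396, -0.345, -0.154)
  tm <- b0 + b1 / sqrt(m) + b2 / m
  fit <- stats::splinefun(tm, log(alpha), method = "natural")
  min(1, max(exp(fit(t)), 1e-12))
}

#' k-sample Anderson-Darling test
#'
#' Rank-based comparison of k empirical distributions, computed from the
#' defining double sum of the criterion with midranks for ties, so the
#' statistic is invariant under strictly increasing transforms of the
#' pooled values. The p-value is either asymptotic (interpolation of the
#' tabulated null quantiles of the standardized statistic) or obtained by
#' permutation of group labels, which is exact up to Monte-Carlo error and
#' preferable for very small samples.
#'
#' @param groups A list of k >= 2 non-empty numeric vectors, or a data
#'   frame together with `value` and `group` column names.
#' @param value,group Column names when `groups` is a data frame.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_permutations Number of label permutations (permutation method).
#' @param seed Seed for the permutation draw.
#' @return An object of classes `ad_ksample` and `htest` with the
#'   criterion `statistic` (`A2akN`), the `standardized` statistic,
#'   `p.value`, group sizes and method details.
#' @export
#' @examples
#' ad_ksample(list(rnorm(20), rnorm(20, 1)))
ad_ksample <- function(groups, value = "value", group = "group",
                       method = c("asymptotic", "permutation"),
                       n_permutations = 9999, seed = 1L) {
  method <- match.arg(method)
  if (is.data.frame(groups)) {
    groups <- split(groups[[value]], groups[[group]])
  }
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  if (any(lengths(groups) == 0L)) {
    stop("every group must be non-empty", call. = FALSE)
  }
  groups <- lapply(groups, as.numeric)
  obs <- ad_ksample_stat(groups)
  k <- length(groups)
  if (method == "asymptotic") {
    p <- ad_pvalue_asymptotic(obs$t, k)
  } else {
    ns <- lengths(groups)
    pool <- unlist(groups, use.names = FALSE)
    idx_end <- cumsum(ns)
    idx_start <- c(1L, idx_end[-k] + 1L)
    p <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_permutations)) {
        perm <- sample(pool)
        gperm <- lapply(seq_len(k), function(i) {
          perm[idx_start[i]:idx_end[i]]
        })
        if (ad_ksample_stat(gperm)$A2 >= obs$A2 - 1e-12) hits <- hits + 1L
      }
      (1 + hits) / (n_permutations + 1)
    })
  }
  structure(
    list(
      statistic = c(A2akN = obs$A2),
      standardized = obs$t,
      sigma = obs$sigma,
      p.value = p,
      k = k,
      n = lengths(groups),
      method = sprintf("%d-sample Anderson-Darling test (midrank ties, %s p)",
                       k, method),
      data.name = deparse(substitute(groups))
    ),
    class = c("ad_ksample", "htest")
  )
}

#' Holm step-down adjustment
#'
#' Validates the input and applies Holm's step-down multiple-comparison
#' adjustment (monotone, capped at 1, returned in input order).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
holm_adjust <- function(p) {
  if (!is.numeric(p) || length(p) == 0L) {
    stop("`p` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "holm")
}

#' Post hoc pairwise Anderson-Darling tests
#'
#' Runs the four prespecified pairwise comparisons of the crossed design
#' (see [psc_posthoc_pairs()]) - or any supplied list of label pairs - and
#' Holm-adjusts the p-values over the family.
#'
#' @param data A data frame of per-event records.
#' @param value,group Column names of the event value and group label.
#' @param pairs List of length-2 character vectors of group labels.
#' @inheritParams ad_ksample
#' @return A data frame with one row per pair: `pair`, `statistic`
#'   (A2akN), `standardized`, `p_raw`, `p_holm`.
#' @export
pairwise_ad_posthoc <- function(data, value = "value", group = "group",
                                pairs = psc_posthoc_pairs(),
                                method = c("asymptotic", "permutation"),
                                n_permutations = 9999, seed = 1L) {
  method <- match.arg(method)
  labels <- unique(as.character(data[[group]]))
  missing_lab <- setdiff(unique(unlist(pairs)), labels)
  if (length(missing_lab)) {
    stop("group label(s) not present in data: ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  }
  res <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    g <- list(
      data[[value]][data[[group]] == pr[1]],
      data[[value]][data[[group]] == pr[2]]
    )
    fit <- ad_ksample(g, method = method, n_permutations = n_permutations,
                      seed = derive_seed(seed, i))
    data.frame(
      pair = paste(pr, collapse = " vs "),
      statistic = unname(fit$statistic),
      standardized = fit$standardized,
      p_raw = fit$p.value
    )
  })
  out <- do.call(rbind, res)
  out$p_holm <- holm_adjust(out$p_raw)
  out
}
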