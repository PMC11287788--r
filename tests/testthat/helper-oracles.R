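# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementations they check.

# k-sample Anderson-Darling criterion (midrank tie handling), evaluated
# directly from its defining double sum over samples and distinct pooled
# values.
ad_bruteforce <- function(groups) {
  pool <- unlist(groups)
  big_n <- length(pool)
  z <- sort(unique(pool))
  total <- 0
  for (i in seq_along(groups)) {
    x <- groups[[i]]
    n_i <- length(x)
    inner <- 0
    for (j in seq_along(z)) {
      l_j <- sum(pool == z[j])
      b_j <- sum(pool < z[j]) + l_j / 2
      m_ij <- sum(x < z[j]) + sum(x == z[j]) / 2
      denom <- b_j * (big_n - b_j) - big_n * l_j / 4
      if (denom > 0) {
        inner <- inner + (l_j / big_n) * (big_n * m_ij - n_i * b_j)^2 / denom
      }
    }
    total <- total + inner / n_i
  }
  total * (big_n - 1) / big_n
}

# Day-by-day estrous-cycle scoring.
cycle_oracle <- function(stages) {
  n_cycles <- 0L
  for (d in 2:length(stages)) {
    if (stages[d] == "P" && stages[d - 1] %in% c("D", "E")) {
      n_cycles <- n_cycles + 1L
    }
  }
  p_first <- integer(0)
  for (d in seq_along(stages)) {
    if (stages[d] == "P" && (d == 1 || stages[d - 1] != "P")) {
      p_first <- c(p_first, d)
    }
  }
  mean_len <- NA_real_
  if (length(p_first) >= 2) {
    gaps <- numeric(0)
    for (i in 2:length(p_first)) {
      gaps <- c(gaps, p_first[i] - p_first[i - 1])
    }
    mean_len <- mean(gaps)
  }
  pct <- c(D = 0, P = 0, E = 0)
  for (s in stages) pct[s] <- pct[s] + 1
  list(n_cycles = n_cycles, mean_cycle_length_d = mean_len,
       pct_days = 100 * pct / length(stages))
}

# Sample-by-sample surge call: any PM value strictly above the threshold.
surge_oracle <- function(pm_values, threshold) {
  for (v in pm_values) {
    if (v > threshold) {
      return(TRUE)
    }
  }
  FALSE
}

# Empirical CDF by sorted-rank construction.
ecdf_oracle <- function(values) {
  v <- sort(unique(values))
  p <- numeric(length(v))
  for (i in seq_along(v)) p[i] <- sum(values <= v[i]) / length(values)
  data.frame(value = v, cumprob = p)
}

# Difference-of-exponentials template used by a few oracles, evaluated
# densely and independently of the package helper.
dense_template <- function(t_s, rise_tau_s, decay_tau_s) {
  w <- (1 - exp(-t_s / rise_tau_s)) * exp(-t_s / decay_tau_s)
  w[t_s < 0] <- 0
  w / max(w)
}
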