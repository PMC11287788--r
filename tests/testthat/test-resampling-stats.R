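# k-sample Anderson-Darling machinery and the hierarchical bootstrap.

test_that("the AD statistic is rank-invariant", {
  set.seed(3)
  g <- list(rnorm(12), rnorm(12, 0.5))
  a1 <- ad_ksample(g)
  a2 <- ad_ksample(lapply(g, function(x) exp(x)))       # strictly increasing
  a3 <- ad_ksample(lapply(g, function(x) x^3 + 5 * x))  # another one
  expect_equal(unname(a1$statistic), unname(a2$statistic), tolerance = 1e-12)
  expect_equal(unname(a1$statistic), unname(a3$statistic), tolerance = 1e-12)
})

test_that("the AD statistic equals the brute-force defining sum", {
  toys <- list(
    list(c(1.2, 3.4, 0.5, 2.2, 5.1), c(2.0, 0.1, 4.4, 1.1, 3.3)),
    list(c(1, 2, 2, 3, 5), c(2, 3, 3, 4, 6)),                   # ties
    list(c(0.4, 1.9, 2.2), c(1.1, 0.8, 3.0, 2.5), c(5, 4, 4.5)) # k = 3
  )
  for (g in toys) {
    expect_equal(unname(ad_ksample(g)$statistic), ad_bruteforce(g),
                 tolerance = 1e-10)
  }
})

test_that("separated samples give a small permutation p", {
  set.seed(5)
  g <- list(rnorm(20, 0), rnorm(20, 10))
  p <- ad_ksample(g, method = "permutation",
                  n_permutations = 10000)$p.value
  expect_lt(p, 0.01)
})

test_that("empty or single groups are rejected", {
  expect_error(ad_ksample(list(1:5)), "at least two groups")
  expect_error(ad_ksample(list(1:5, numeric(0))), "non-empty")
})

test_that("the four prespecified pairs are compared and Holm-adjusted", {
  set.seed(6)
  base <- rnorm(25)
  df <- data.frame(
    value = c(base, base, base, base),
    group = rep(psc_groups(), each = 25)
  )
  res <- pairwise_ad_posthoc(df)
  expect_equal(nrow(res), 4)
  expect_equal(res$pair, vapply(psc_posthoc_pairs(), paste,
                                character(1), collapse = " vs "))
  expect_true(all(res$p_holm == 1))  # identical samples: adjusted p capped

  # one strongly separated pair: its Holm p is 4x the raw p (first step)
  df2 <- df
  df2$value[df2$group == "STD-ALPS"] <-
    df2$value[df2$group == "STD-ALPS"] + 50
  res2 <- pairwise_ad_posthoc(df2)
  sep <- grepl("STD-ALPS", res2$pair)
  expect_equal(res2$p_holm[which.min(res2$p_raw)],
               min(res2$p_raw) * 4, tolerance = 1e-12)
  expect_true(all(res2$p_raw[sep] < res2$p_raw[!sep] | !sep[sep]))

  expect_error(
    pairwise_ad_posthoc(df[df$group != "LBN-CON", ]),
    "LBN-CON"
  )
})

test_that("Holm adjustment matches hand computation and its bounds", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(c(0.001, 0.20, 0.50, 0.70)),
               c(0.004, 0.60, 1.00, 1.00))
  expect_equal(holm_adjust(0.37), 0.37)
  expect_error(holm_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= pmin(1, length(p) * p)))  # Bonferroni bound
  }
})

test_that("bootstrap CIs collapse for constant groups", {
  df <- data.frame(
    value = rep(c(2, 5), each = 12),
    group = rep(c("A", "B"), each = 12),
    cell = rep(sprintf("c%d", 1:8), each = 3)
  )
  bt <- hierarchical_bootstrap(df, unit = "cell",
                               spec = bootstrap_spec(n_iterations = 100,
                                                     seed = 1),
                               pairs = list(c("A", "B")))
  expect_equal(bt$groups$ci_low, bt$groups$ci_high)
  expect_equal(bt$groups$estimate, c(2, 5))
  expect_equal(bt$pairs$estimate, -3)
  expect_equal(bt$pairs$ci_low, -3)
})

test_that("bootstrap defaults follow the study procedure", {
  sp <- bootstrap_spec()
  expect_equal(sp$n_iterations, 5000L)
  expect_equal(sp$lower_percentile, 2.5)
  expect_equal(sp$upper_percentile, 97.5)
  expect_equal(sp$resample_unit, "cell")
})

test_that("unit resampling with singleton cells equals the event bootstrap", {
  set.seed(10)
  df <- data.frame(
    value = rnorm(40),
    group = rep(c("A", "B"), each = 20),
    cell = sprintf("c%02d", 1:40)
  )
  b1 <- hierarchical_bootstrap(df, unit = "cell",
                               spec = bootstrap_spec(n_iterations = 500,
                                                     seed = 3),
                               pairs = list(c("A", "B")))
  b2 <- hierarchical_bootstrap(df, unit = "cell",
                               spec = bootstrap_spec(n_iterations = 500,
                                                     resample_unit = "event",
                                                     seed = 3),
                               pairs = list(c("A", "B")))
  expect_equal(b1$groups$estimate, b2$groups$estimate)
  expect_equal(b1$pairs$ci_low, b2$pairs$ci_low)
})

test_that("bootstrap CI width shrinks with sample size", {
  width_at <- function(n) {
    set.seed(20)
    df <- data.frame(value = rnorm(n), group = "A",
                     cell = sprintf("c%04d", seq_len(n)))
    bt <- hierarchical_bootstrap(df, unit = "cell",
                                 spec = bootstrap_spec(n_iterations = 400,
                                                       seed = 4),
                                 pairs = list())
    bt$groups$ci_high - bt$groups$ci_low
  }
  expect_lt(width_at(400), width_at(25))
})

test_that("groups without resampleable units are rejected", {
  df <- data.frame(value = 1:3, group = c("A", "A", "B"),
                   cell = c("c1", "c1", "c2"))
  expect_error(
    hierarchical_bootstrap(df, unit = "cell",
                           spec = bootstrap_spec(n_iterations = 10),
                           pairs = list(c("A", "C"))),
    "pair labels"
  )
})

test_that("compare_groups assembles omnibus, post hoc and bootstrap", {
  set.seed(30)
  df <- data.frame(
    value = c(rnorm(40), rnorm(40), rnorm(40, 1.5), rnorm(40, 1.5)),
    group = rep(psc_groups(), each = 40),
    cell = rep(sprintf("c%02d", 1:16), each = 10)
  )
  cmp <- compare_groups(df, unit = "cell",
                        boot_spec = bootstrap_spec(n_iterations = 300,
                                                   seed = 2))
  expect_s3_class(cmp, "group_comparison")
  expect_lt(cmp$omnibus$p.value, 0.05)
  tbl <- comparison_table(cmp)
  expect_equal(nrow(tbl), 4)
  expect_true(all(tbl$p_holm >= tbl$p_raw))
  expect_true(all(tbl$ci_low <= tbl$mean_diff &
                    tbl$mean_diff <= tbl$ci_high))
})
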