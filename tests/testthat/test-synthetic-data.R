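# Generators: traces, hormone profiles, cycle sequences, cohorts.

test_that("degenerate trace spec gives a constant trace and empty truth", {
  sim <- generate_psc_trace(trace_spec(duration_s = 2, event_rate_hz = 0,
                                       noise_sd_pa = 0, baseline_pa = -20,
                                       seed = 1))
  expect_equal(length(sim$trace$samples_pa), 2 * 10000)
  expect_true(all(sim$trace$samples_pa == -20))
  expect_equal(nrow(sim$truth), 0)
})

test_that("identical seeds give bit-identical generator output", {
  sp <- trace_spec(duration_s = 5, event_rate_hz = 2, seed = 33)
  expect_identical(generate_psc_trace(sp), generate_psc_trace(sp))
  expect_identical(
    generate_lh_profiles(10, seed = 4),
    generate_lh_profiles(10, seed = 4)
  )
  expect_identical(
    generate_cycle_sequences(5, seed = 4),
    generate_cycle_sequences(5, seed = 4)
  )
  sp2 <- cohort_spec(n_dams_per_group = 2, seed = 9)
  expect_identical(generate_cort_profiles(sp2), generate_cort_profiles(sp2))
})

test_that("invalid trace specs are rejected", {
  expect_error(trace_spec(duration_s = 0), "duration_s")
  expect_error(trace_spec(sample_rate_hz = -1), "sample_rate_hz")
  expect_error(trace_spec(event_rate_hz = -0.1), "event_rate_hz")
  expect_error(trace_spec(decay_tau_ms = 0), "decay_tau_ms")
})

test_that("ground-truth event counts follow the Poisson mean", {
  # 1 Hz for 240 s over 200 seeds: mean count within 3 SE of 240
  counts <- vapply(1:200, function(s) {
    sim <- generate_psc_trace(trace_spec(
      duration_s = 240, event_rate_hz = 1, noise_sd_pa = 0,
      amplitude_cv = 0, seed = s
    ))
    expect_true(!is.unsorted(sim$truth$onset_time_s))
    expect_true(all(sim$truth$onset_time_s >= 0 &
                      sim$truth$onset_time_s <= 240))
    nrow(sim$truth)
  }, numeric(1))
  se <- sqrt(240) / sqrt(200)
  expect_lt(abs(mean(counts) - 240), 3 * se)
})

test_that("trace round-trips through CSV and ATF text", {
  sim <- generate_psc_trace(trace_spec(duration_s = 0.05, event_rate_hz = 5,
                                       seed = 2))
  for (fmt in c("csv", "atf")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_trace(sim$trace, f, format = fmt)
    back <- read_trace(f, format = fmt)
    expect_equal(back$samples_pa, sim$trace$samples_pa, tolerance = 1e-6)
    expect_equal(back$sample_rate_hz, 10000, tolerance = 1e-6)
    unlink(f)
  }
})

test_that("LH profiles censor at the assay maximum and label surges", {
  # no surges, low flat baseline: nothing exceeds a positive threshold
  lh0 <- generate_lh_profiles(20, surge_probability = 0,
                              am_baseline_mean = 0.5, am_baseline_sd = 0.1,
                              seed = 5)
  expect_true(all(!lh0$true_surge))
  expect_true(all(lh0$conc_ng_ml[lh0$period == "PM"] < 3.8))

  # a peak far above the assay maximum is stored at 40 with a flag
  lh1 <- generate_lh_profiles(200, surge_probability = 1,
                              surge_peak_meanlog = log(80),
                              surge_peak_sdlog = 0, seed = 6)
  expect_true(all(lh1$conc_ng_ml <= 40))
  peaks <- tapply(lh1$conc_ng_ml, lh1$animal_id, max)
  expect_true(all(peaks == 40))
  expect_true(any(lh1$censored))
})

test_that("surge classifier recovers generator labels when peaks are high", {
  lh <- generate_lh_profiles(500, surge_probability = 0.5, seed = 11)
  by_animal <- split(lh, lh$animal_id)
  calls <- vapply(by_animal, function(a) classify_surge(a)$surged,
                  logical(1))
  truth <- vapply(by_animal, function(a) a$true_surge[1], logical(1))
  expect_gte(mean(calls == truth), 0.95)
})

test_that("cycle sequences honour deterministic and absorbing laws", {
  det <- generate_cycle_sequences(3, n_days = 8,
                                  transition_law = c("D", "D", "P", "E"))
  expect_equal(det$stage[det$animal_id == 2],
               rep(c("D", "D", "P", "E"), 2))

  absorbing <- matrix(c(1, 0, 0, 0, 0, 1, 1, 0, 0), 3, byrow = TRUE,
                      dimnames = list(c("D", "P", "E"), c("D", "P", "E")))
  allD <- generate_cycle_sequences(4, n_days = 10,
                                   transition_law = absorbing, seed = 2)
  expect_true(all(allD$stage == "D"))

  bad <- matrix(rep(1, 9), 3)
  expect_error(generate_cycle_sequences(2, transition_law = bad),
               "summing to 1")
  expect_error(generate_cycle_sequences(2, transition_law = c("D", "X")),
               "D, P, E")
})

test_that("default cycle law yields 4-5 day cycles over 21 days", {
  cyc <- generate_cycle_sequences(200, seed = 7)
  counts <- vapply(split(cyc$stage, cyc$animal_id),
                   function(s) cycle_metrics(s)$n_cycles, numeric(1))
  expect_gte(mean(counts), 4)
  expect_lte(mean(counts), 5)
})

test_that("cort generator collapses to constants without noise or effects", {
  sp <- cohort_spec(
    n_dams_per_group = 2,
    cort_fold = c("STD-CON" = 1, "STD-ALPS" = 1,
                  "LBN-CON" = 1, "LBN-ALPS" = 1),
    dam_sd_log10 = 0, mouse_sd_log10 = 0, resid_sd_log10 = 0, seed = 3
  )
  cort <- generate_cort_profiles(sp)
  expect_equal(cort$conc_ng_ml, rep(30, nrow(cort)))
})

test_that("cort post/pre fold change is recovered as a geometric ratio", {
  sp <- cohort_spec(
    n_dams_per_group = 40,  # ~1000+ mice at 5-8 pups/litter
    cort_fold = c("STD-CON" = 3, "STD-ALPS" = 3,
                  "LBN-CON" = 3, "LBN-ALPS" = 3),
    seed = 8
  )
  cort <- generate_cort_profiles(sp)
  gm <- tapply(log10(cort$conc_ng_ml), cort$time, mean)
  expect_equal(10^(gm[["post"]] - gm[["pre"]]), 3, tolerance = 0.05)
})

test_that("cort values respect the EIA reportable range", {
  sp <- cohort_spec(
    n_dams_per_group = 3, cort_baseline_ng_ml = 600,
    cort_fold = c("STD-CON" = 2.9, "STD-ALPS" = 9,
                  "LBN-CON" = 2.9, "LBN-ALPS" = 9),
    seed = 10
  )
  cort <- generate_cort_profiles(sp)
  expect_true(all(cort$conc_ng_ml <= 1000))
  expect_true(all(cort$conc_ng_ml >= 3.9))
  expect_true(any(cort$censored))  # post values of stressed groups clip
})

test_that("cohort litters stay within the normalized 5-8 pup range", {
  cohort <- generate_cohort(cohort_spec(n_dams_per_group = 6, seed = 2))
  sizes <- table(cohort$dam_id)
  expect_true(all(sizes >= 5 & sizes <= 8))
  expect_equal(sort(unique(cohort$group)), sort(psc_groups()))
  expect_error(cohort_spec(pups_per_litter = c(3, 8)), "5-8")
})

test_that("cohort specs round-trip through YAML", {
  sp <- cohort_spec(n_dams_per_group = 4, seed = 12)
  f <- tempfile(fileext = ".yaml")
  write_cohort_spec(sp, f)
  back <- read_cohort_spec(f)
  expect_equal(back, sp)
  unlink(f)
})
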