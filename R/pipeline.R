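# End-to-end synthetic study: simulate -> detect -> summarize -> compare ->
# score, with provenance and a JSON report.

#' Pipeline configuration
#'
#' Bundles the sub-configurations of every stage with a master seed. All
#' per-stage randomness is derived deterministically from `seed`, so a
#' given configuration is fully reproducible. Defaults scale the study
#' design to a desk-size synthetic cohort: six recorded mice per group
#' with 2-3 cells each (about 15 cells/group) and 4 min traces.
#'
#' @param seed Master integer seed, echoed into every output.
#' @param cohort A [cohort_spec()] or path to a YAML file of its fields.
#' @param trace A [trace_spec()]; its `event_rate_hz` and `seed` are
#'   overridden per cell from the cohort spec and master seed.
#' @param detection A [detection_config()].
#' @param metric A [metric_config()].
#' @param bootstrap A [bootstrap_spec()]; its seed is derived from `seed`.
#' @param surge A [surge_rule()].
#' @param mice_per_group Recorded mice per group for electrophysiology.
#' @param cells_per_mouse Range of cells recorded per mouse.
#' @param out_dir Optional output directory for CSV intermediates and the
#'   JSON report.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, cohort = cohort_spec(),
                       trace = trace_spec(), detection = detection_config(),
                       metric = metric_config(),
                       bootstrap = bootstrap_spec(),
                       surge = surge_rule(), mice_per_group = 6,
                       cells_per_mouse = c(2, 3), out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort_spec(cohort)
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(trace, "trace_spec"),
            inherits(detection, "detection_config"),
            inherits(metric, "metric_config"),
            inherits(bootstrap, "bootstrap_spec"),
            inherits(surge, "surge_rule"))
  check_scalar(seed, "seed", integerish = TRUE)
  check_scalar(mice_per_group, "mice_per_group", positive = TRUE,
               integerish = TRUE)
  structure(
    list(
      seed = as.integer(seed), cohort = cohort, trace = trace,
      detection = detection, metric = metric, bootstrap = bootstrap,
      surge = surge, mice_per_group = as.integer(mice_per_group),
      cells_per_mouse = as.integer(cells_per_mouse), out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Read and write cohort specifications as YAML
#'
#' @param spec A [cohort_spec()].
#' @param path YAML file path.
#' @return `read_cohort_spec()` returns a [cohort_spec()];
#'   `write_cohort_spec()` returns `path` invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  fields <- unclass(spec)
  fields$groups <- NULL
  for (nm in c("event_rate_hz", "surge_probability", "cort_fold")) {
    fields[[nm]] <- as.list(fields[[nm]])
  }
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  fields <- yaml::read_yaml(path)
  for (nm in c("event_rate_hz", "surge_probability", "cort_fold")) {
    if (!is.null(fields[[nm]])) fields[[nm]] <- unlist(fields[[nm]])
  }
  do.call(cohort_spec, fields)
}

#' Run the end-to-end synthetic study
#'
#' Executes every stage on synthetic data: (1) draw the nested cohort
#' (dam -> litter -> mouse) and record per-group traces for the assigned
#' cells; (2) detect PSCs in every trace; (3) compute per-cell summaries
#' and pool event records; (4) compare the four groups' interevent-interval
#' and amplitude distributions (omnibus and post hoc Anderson-Darling,
#' hierarchical bootstrap); (5) score synthetic LH profiles for surges,
#' corticosterone responses and estrous cycles. Identical seeds give
#' identical reports; intermediate tables and a JSON report are written
#' when `out_dir` is set.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report`; see the vignette for the layout.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(
#'   seed = 7,
#'   cohort = cohort_spec(n_dams_per_group = 2),
#'   trace = trace_spec(duration_s = 30),
#'   bootstrap = bootstrap_spec(n_iterations = 200),
#'   mice_per_group = 2, cells_per_mouse = c(1, 2)
#' )
#' rep <- run_pipeline(cfg)
#' rep$surge$proportions
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  ## stage 1+2+3: simulate traces, detect, summarize per cell
  cohort <- generate_cohort(config$cohort)
  cells <- assign_cells(cohort, config)
  message(sprintf("[simulate] %d cells across %d mice, %d dams",
                  nrow(cells), length(unique(cells$mouse_id)),
                  length(unique(cells$dam_id))))
  summaries <- vector("list", nrow(cells))
  pooled <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    spec_i <- config$trace
    spec_i$event_rate_hz <-
      unname(config$cohort$event_rate_hz[cells$group[i]])
    spec_i$seed <- derive_seed(config$seed, 1000L + i)
    sim <- generate_psc_trace(spec_i)
    ev <- detect_events(sim$trace, config$detection)
    sm <- summarize_cell(ev, sim$trace, config = config$metric)
    summaries[[i]] <- data.frame(
      cell_id = cells$cell_id[i], mouse_id = cells$mouse_id[i],
      dam_id = cells$dam_id[i], group = cells$group[i],
      n_events = sm$n_events, frequency_hz = sm$frequency_hz,
      mean_interval_s = sm$mean_interval_s,
      mean_amplitude_pa = sm$mean_amplitude_pa,
      decay_time_80_20_ms = sm$decay_time_80_20_ms
    )
    pooled[[i]] <- pool_cell_events(cells[i, ], ev, sm)
  }
  cell_summary <- do.call(rbind, summaries)
  events_pooled <- do.call(rbind, pooled)
  zero_cells <- sum(cell_summary$n_events == 0)
  if (zero_cells > 0) {
    message(sprintf(
      "[metrics] %d cell(s) without PSCs contribute frequency 0 only",
      zero_cells
    ))
  }
  message(sprintf("[detect] %d events detected; %d interval records pooled",
                  sum(cell_summary$n_events),
                  sum(!is.na(events_pooled$interval_s))))

  ## stage 4: group comparison on intervals and eligible amplitudes
  boot <- config$bootstrap
  boot$seed <- derive_seed(config$seed, 2L)
  ints <- events_pooled[!is.na(events_pooled$interval_s), ]
  amps <- events_pooled[!is.na(events_pooled$amplitude_pa), ]
  comparison <- list(
    interval = compare_groups(ints, value = "interval_s", group = "group",
                              unit = "cell_id", boot_spec = boot),
    amplitude = compare_groups(amps, value = "amplitude_pa",
                               group = "group", unit = "cell_id",
                               boot_spec = boot)
  )
  message(sprintf(
    "[compare] omnibus AD p: interval %.3g, amplitude %.3g",
    comparison$interval$omnibus$p.value,
    comparison$amplitude$omnibus$p.value
  ))

  ## stage 5: endocrine scoring
  surge <- simulate_surge_scores(config)
  cort <- generate_cort_profiles(replace_seed(config$cohort,
                                              derive_seed(config$seed, 4L)))
  cort_summary <- cort_ratio_by_group(cort)
  cycles <- generate_cycle_sequences(
    n_animals = 4 * config$cohort$n_dams_per_group,
    seed = derive_seed(config$seed, 5L)
  )
  cyc_list <- lapply(split(cycles$stage, cycles$animal_id), cycle_metrics)
  cycle_summary <- data.frame(
    n_animals = length(cyc_list),
    mean_n_cycles = mean(vapply(cyc_list, `[[`, numeric(1), "n_cycles")),
    mean_cycle_length_d = mean(
      vapply(cyc_list, `[[`, numeric(1), "mean_cycle_length_d"),
      na.rm = TRUE
    )
  )
  message(sprintf(
    "[score] surge proportions: %s",
    paste(sprintf("%s %.2f", surge$proportions$group,
                  surge$proportions$proportion), collapse = ", ")
  ))

  report <- structure(
    list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("pscpipe")),
      counts = list(
        cells = nrow(cells),
        events_detected = sum(cell_summary$n_events),
        interval_records = nrow(ints),
        amplitude_records = nrow(amps)
      ),
      cell_summary = cell_summary,
      group_summary = group_means(cell_summary),
      comparison = comparison,
      surge = surge,
      cort_summary = cort_summary,
      cycle_summary = cycle_summary,
      config = config_echo(config)
    ),
    class = "run_report"
  )
  if (!is.null(out_dir)) {
    utils::write.csv(cell_summary, file.path(out_dir, "cell_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(events_pooled, file.path(out_dir, "events_pooled.csv"),
                     row.names = FALSE)
    comparison_table(comparison$interval,
                     file.path(out_dir, "comparison_interval.csv"))
    comparison_table(comparison$amplitude,
                     file.path(out_dir, "comparison_amplitude.csv"))
    utils::write.csv(surge$scores, file.path(out_dir, "surge_scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# Electrophysiology cell assignment: mice_per_group mice drawn across the
# group's litters, alternating 2-3 cells per mouse.
assign_cells <- function(cohort, config) {
  with_seed(derive_seed(config$seed, 1L), {
    rows <- lapply(psc_groups(), function(g) {
      mice <- cohort[cohort$group == g, ]
      n_take <- min(config$mice_per_group, nrow(mice))
      take <- mice[sample.int(nrow(mice), n_take), ]
      ncell <- rep_len(seq(config$cells_per_mouse[1],
                           config$cells_per_mouse[length(
                             config$cells_per_mouse)]),
                       n_take)
      do.call(rbind, lapply(seq_len(n_take), function(i) {
        data.frame(
          dam_id = take$dam_id[i], group = g, mouse_id = take$mouse_id[i],
          cell_index = seq_len(ncell[i])
        )
      }))
    })
    out <- do.call(rbind, rows)
    out$cell_id <- sprintf("cell%04d", seq_len(nrow(out)))
    out
  })
}

# Per-event records for the resampling stage: backward intervals (NA for
# the first event) and eligibility-filtered amplitudes (NA when the event
# is not amplitude-eligible).
pool_cell_events <- function(cell, events, summary) {
  n <- nrow(events)
  if (n == 0L) {
    return(NULL)
  }
  amp_ok <- events$amplitude_pa %in% summary$eligible_amplitudes_pa
  data.frame(
    cell_id = cell$cell_id, mouse_id = cell$mouse_id,
    dam_id = cell$dam_id, group = cell$group,
    peak_time_s = events$peak_time_s,
    interval_s = c(NA_real_, diff(events$peak_time_s)),
    amplitude_pa = ifelse(amp_ok, events$amplitude_pa, NA_real_)
  )
}

simulate_surge_scores <- function(config) {
  groups <- psc_groups()
  n_per_group <- 2L * config$cohort$n_dams_per_group
  scores <- do.call(rbind, lapply(seq_along(groups), function(gi) {
    g <- groups[gi]
    lh <- generate_lh_profiles(
      n_animals = n_per_group,
      surge_probability = unname(config$cohort$surge_probability[g]),
      seed = derive_seed(config$seed, 30L + gi)
    )
    per_animal <- lapply(split(lh, lh$animal_id), function(a) {
      cls <- classify_surge(a, config$surge)
      data.frame(
        group = g, animal_id = a$animal_id[1], surged = cls$surged,
        max_pm_lh = cls$max_pm, true_surge = a$true_surge[1]
      )
    })
    do.call(rbind, per_animal)
  }))
  rownames(scores) <- NULL
  props <- stats::aggregate(surged ~ group, scores, mean)
  names(props)[2] <- "proportion"
  list(scores = scores, proportions = props,
       label_accuracy = mean(scores$surged == scores$true_surge))
}

replace_seed <- function(spec, seed) {
  spec$seed <- as.integer(seed)
  spec
}

cort_ratio_by_group <- function(cort) {
  gm <- stats::aggregate(log10(conc_ng_ml) ~ group + time, cort, mean)
  names(gm)[3] <- "mean_log10"
  wide <- stats::reshape(gm, idvar = "group", timevar = "time",
                         direction = "wide")
  data.frame(
    group = wide$group,
    geo_mean_pre = 10^wide$mean_log10.pre,
    geo_mean_post = 10^wide$mean_log10.post,
    post_pre_ratio = 10^(wide$mean_log10.post - wide$mean_log10.pre)
  )
}

group_means <- function(cell_summary) {
  agg <- function(col) {
    stats::aggregate(cell_summary[[col]],
                     list(group = cell_summary$group),
                     function(x) mean(x, na.rm = TRUE))$x
  }
  groups <- sort(unique(cell_summary$group))
  data.frame(
    group = groups,
    mean_frequency_hz = agg("frequency_hz"),
    mean_interval_s = agg("mean_interval_s"),
    mean_amplitude_pa = agg("mean_amplitude_pa"),
    mean_decay_ms = agg("decay_time_80_20_ms")
  )
}

config_echo <- function(config) {
  list(
    seed = config$seed,
    trace = unclass(config$trace),
    detection = unclass(config$detection),
    metric = unclass(config$metric),
    bootstrap = unclass(config$bootstrap),
    surge = unclass(config$surge),
    cohort = {
      ch <- unclass(config$cohort)
      ch$event_rate_hz <- as.list(ch$event_rate_hz)
      ch$surge_probability <- as.list(ch$surge_probability)
      ch$cort_fold <- as.list(ch$cort_fold)
      ch
    },
    mice_per_group = config$mice_per_group,
    cells_per_mouse = config$cells_per_mouse
  )
}

report_to_json <- function(report) {
  list(
    seed = report$seed,
    package_version = report$package_version,
    counts = report$counts,
    group_summary = report$group_summary,
    comparison = list(
      interval = list(
        omnibus_A2 = unname(report$comparison$interval$omnibus$statistic),
        omnibus_p = report$comparison$interval$omnibus$p.value,
        pairs = comparison_table(report$comparison$interval)
      ),
      amplitude = list(
        omnibus_A2 = unname(report$comparison$amplitude$omnibus$statistic),
        omnibus_p = report$comparison$amplitude$omnibus$p.value,
        pairs = comparison_table(report$comparison$amplitude)
      )
    ),
    surge_proportions = report$surge$proportions,
    cort_summary = report$cort_summary,
    cycle_summary = report$cycle_summary,
    config = report$config
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d, pscpipe %s\n", x$seed,
              x$package_version))
  cat(sprintf("  %d cells, %d events detected\n", x$counts$cells,
              x$counts$events_detected))
  cat("Per-group cell means:\n")
  print(x$group_summary, digits = 3)
  cat(sprintf("Interval omnibus AD p = %.4g; amplitude omnibus AD p = %.4g\n",
              x$comparison$interval$omnibus$p.value,
              x$comparison$amplitude$omnibus$p.value))
  cat("Surge proportions:\n")
  print(x$surge$proportions, digits = 3)
  invisible(x)
}

#' Recompute the printed worked numbers
#'
#' Recomputes, from the printed group summaries of the study report, each
#' worked statistic that is reconstructible at full precision: the PND4
#' litter-mass two-sample t and Cohen's d from means/SEMs/sizes, and the
#' post hoc contrast t-ratios whose printed estimate and SEM carry enough
#' digits (dam mass, PND11 offspring mass, testes mass, uterine mass).
#' Tolerance is +/- 0.02 because the printed inputs are rounded to 1-2
#' decimals.
#'
#' @return A data frame with columns `target`, `printed`, `recomputed`,
#'   `tolerance`, `pass`; attribute `all_pass` aggregates the checks.
#' @export
#' @examples
#' validate_printed_examples()
validate_printed_examples <- function() {
  pnd4 <- two_sample_t_from_summary(2.8, 0.06, 25, 2.9, 0.06, 24)
  rows <- list(
    list("litter_mass_pnd4_t", -1.18, pnd4$t),
    list("litter_mass_pnd4_cohens_d", -0.34,
         cohens_d_from_summary(2.8, 0.06, 25, 2.9, 0.06, 24)),
    list("dam_mass_contrast_t", -2.20, contrast_t(-1.23, 0.562)),
    list("pnd11_mass_contrast_t", 2.87, contrast_t(0.55, 0.192)),
    list("testes_mass_contrast_t", 4.35, contrast_t(15.52, 3.565)),
    list("uterine_mass_contrast_t", -23.95, contrast_t(-71.38, 2.981))
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(
      target = r[[1]], printed = r[[2]], recomputed = r[[3]],
      tolerance = 0.02, pass = abs(r[[3]] - r[[2]]) <= 0.02
    )
  }))
  attr(out, "all_pass") <- all(out$pass)
  out
}
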