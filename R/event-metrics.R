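# Per-cell PSC summaries: frequency, intervals, amplitude eligibility,
# isolated-event averaging and 80-20% decay time.

#' Event-metric configuration
#'
#' Eligibility windows for the per-cell summaries. Amplitudes are analyzed
#' only for events with a backward interevent interval of at least 200 ms
#' (inclusive); events are "isolated" (used for waveform averaging) only
#' when both the backward and the forward gap to the adjacent event peaks
#' strictly exceed 200 ms. The asymmetry of the comparisons (>= vs >) is
#' deliberate and follows the definitions of the two filters.
#'
#' @param amplitude_min_backward_interval_s Inclusive backward-interval
#'   threshold for amplitude eligibility (s).
#' @param isolated_min_interval_s Exclusive two-sided gap threshold for
#'   isolated events (s).
#' @param waveform_pre_ms,waveform_post_ms Snippet extent around each
#'   isolated peak for waveform averaging (ms).
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(amplitude_min_backward_interval_s = 0.200,
                          isolated_min_interval_s = 0.200,
                          waveform_pre_ms = 10, waveform_post_ms = 100) {
  check_scalar(amplitude_min_backward_interval_s,
               "amplitude_min_backward_interval_s", positive = TRUE)
  check_scalar(isolated_min_interval_s, "isolated_min_interval_s",
               positive = TRUE)
  check_scalar(waveform_pre_ms, "waveform_pre_ms", positive = TRUE)
  check_scalar(waveform_post_ms, "waveform_post_ms", positive = TRUE)
  structure(
    list(
      amplitude_min_backward_interval_s = amplitude_min_backward_interval_s,
      isolated_min_interval_s = isolated_min_interval_s,
      waveform_pre_ms = waveform_pre_ms,
      waveform_post_ms = waveform_post_ms
    ),
    class = "metric_config"
  )
}

#' PSC frequency
#'
#' Number of events divided by the recording duration. Zero events is a
#' meaningful zero (cells without PSCs contribute frequency 0).
#'
#' @param events A `psc_events` data frame (or anything with a
#'   `peak_time_s` column), or a numeric vector of peak times.
#' @param duration_s Recording duration (s, > 0).
#' @return Frequency in Hz.
#' @export
#' @examples
#' psc_frequency(data.frame(peak_time_s = seq(0.5, 230, by = 10)), 240)
psc_frequency <- function(events, duration_s) {
  check_scalar(duration_s, "duration_s", positive = TRUE)
  length(event_peak_times(events)) / duration_s
}

event_peak_times <- function(events) {
  if (is.numeric(events)) {
    return(as.numeric(events))
  }
  if (is.data.frame(events) && "peak_time_s" %in% names(events)) {
    return(events$peak_time_s)
  }
  stop("`events` must be a numeric vector or have a `peak_time_s` column",
       call. = FALSE)
}

#' Backward interevent intervals
#'
#' The interevent interval of an event is the backward interval from its
#' peak to the previous event's peak. The first event of a recording has no
#' known interval and is excluded, so a recording with `n` events yields
#' `n - 1` intervals.
#'
#' @inheritParams psc_frequency
#' @return Numeric vector of intervals (s).
#' @export
#' @examples
#' interevent_intervals(c(1.0, 1.5, 2.1))
interevent_intervals <- function(events) {
  t_s <- event_peak_times(events)
  if (is.unsorted(t_s, strictly = FALSE)) {
    stop("events must be ordered by peak time", call. = FALSE)
  }
  diff(t_s)
}

#' Amplitude eligibility filter
#'
#' Amplitudes are retained for events whose backward interevent interval is
#' at least `amplitude_min_backward_interval_s` (inclusive); the first
#' event of a recording is retained when it is preceded by strictly more
#' than that much recording time.
#'
#' @param events A `psc_events` data frame with `peak_time_s` and
#'   `amplitude_pa` columns, ordered by peak time.
#' @param recording_start_s Time at which the recording started (s).
#' @param config A [metric_config()].
#' @return Numeric vector of eligible amplitudes (pA).
#' @export
#' @examples
#' ev <- data.frame(peak_time_s = c(0.15, 0.40, 0.55),
#'                  amplitude_pa = c(10, 20, 30))
#' eligible_amplitudes(ev)  # only the 20 pA event qualifies
eligible_amplitudes <- function(events, recording_start_s = 0,
                                config = metric_config()) {
  stopifnot(is.data.frame(events),
            all(c("peak_time_s", "amplitude_pa") %in% names(events)))
  n <- nrow(events)
  if (n == 0L) {
    return(numeric(0))
  }
  t_s <- events$peak_time_s
  if (is.unsorted(t_s)) {
    stop("events must be ordered by peak time", call. = FALSE)
  }
  thr <- config$amplitude_min_backward_interval_s
  keep <- logical(n)
  keep[1] <- (t_s[1] - recording_start_s) > thr
  if (n > 1L) {
    # 1 ns slack so the inclusive boundary survives binary rounding of times
    keep[-1] <- diff(t_s) >= thr - 1e-9
  }
  events$amplitude_pa[keep]
}

# Indices of isolated events: both the backward and forward gaps between
# adjacent peaks strictly exceed the threshold. The first/last events use
# the gap to the recording start/end, symmetrically with the amplitude
# first-event rule.
isolated_event_indices <- function(peak_times_s, duration_s,
                                   threshold_s = 0.2,
                                   recording_start_s = 0) {
  n <- length(peak_times_s)
  if (n == 0L) {
    return(integer(0))
  }
  back <- c(peak_times_s[1] - recording_start_s, diff(peak_times_s))
  fwd <- c(diff(peak_times_s), duration_s - peak_times_s[n])
  which(back > threshold_s & fwd > threshold_s)
}

#' Average isolated events of a cell
#'
#' Selects isolated events (gap > `isolated_min_interval_s` to the adjacent
#' event peaks in both directions), cuts peak-aligned snippets from the
#' trace, averages them and peak-normalizes the average.
#'
#' @param events A `psc_events` data frame ordered by peak time.
#' @param trace The [psc_trace()] the events came from.
#' @param config A [metric_config()].
#' @return A list of class `psc_waveform` with `waveform` (normalized
#'   average, peak = 1), `sample_rate_hz`, `peak_index`, `n_events`; or
#'   `NULL` when no isolated events are available.
#' @export
isolated_event_average <- function(events, trace, config = metric_config()) {
  stopifnot(inherits(trace, "psc_trace"), is.data.frame(events))
  if (nrow(events) == 0L) {
    return(NULL)
  }
  fs <- trace$sample_rate_hz
  iso <- isolated_event_indices(events$peak_time_s, trace$duration_s,
                                config$isolated_min_interval_s)
  pre <- round(config$waveform_pre_ms / 1000 * fs)
  post <- round(config$waveform_post_ms / 1000 * fs)
  n <- length(trace$samples_pa)
  snippets <- list()
  for (i in iso) {
    pk <- round(events$peak_time_s[i] * fs) + 1L
    if (pk - pre < 1L || pk + post > n) next  # snippet leaves the record
    snip <- trace$samples_pa[(pk - pre):(pk + post)]
    base <- events$baseline_pa[i]
    if (is.null(base) || is.na(base)) base <- snip[1]
    snippets[[length(snippets) + 1L]] <- snip - base
  }
  if (length(snippets) == 0L) {
    return(NULL)
  }
  avg <- rowMeans(do.call(cbind, snippets))
  pk_idx <- which.max(abs(avg))
  structure(
    list(
      waveform = avg / avg[pk_idx],
      sample_rate_hz = fs,
      peak_index = pk_idx,
      n_events = length(snippets)
    ),
    class = "psc_waveform"
  )
}

#' 80-20% decay time
#'
#' Time between the first post-peak crossings of 80% and 20% of the peak,
#' with linear interpolation between samples. For a mono-exponential decay
#' with time constant `tau` this equals `tau * log(4)`.
#'
#' @param waveform Numeric waveform (positive-going, peak is the maximum)
#'   or a `psc_waveform` from [isolated_event_average()].
#' @param sample_rate_hz Sampling rate (Hz); taken from the `psc_waveform`
#'   when one is given.
#' @return Decay time in ms.
#' @export
#' @examples
#' tau <- 10  # ms
#' t_ms <- seq(0, 200, by = 0.1)
#' decay_time_80_20(exp(-t_ms / tau), sample_rate_hz = 10000)  # ~ tau*log(4)
decay_time_80_20 <- function(waveform, sample_rate_hz = NULL) {
  if (inherits(waveform, "psc_waveform")) {
    sample_rate_hz <- waveform$sample_rate_hz
    waveform <- waveform$waveform
  }
  check_scalar(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  if (length(waveform) < 3L) {
    stop("waveform too short", call. = FALSE)
  }
  pk <- which.max(waveform)
  peak <- waveform[pk]
  if (peak <= 0) {
    stop("waveform has no positive peak", call. = FALSE)
  }
  post <- waveform[pk:length(waveform)]
  t80 <- crossing_time(post, 0.8 * peak)
  t20 <- crossing_time(post, 0.2 * peak)
  if (is.na(t80) || is.na(t20)) {
    stop("waveform does not decay below 20% of its peak", call. = FALSE)
  }
  (t20 - t80) / sample_rate_hz * 1000
}

# First downward crossing of `level` in `x` (x[1] assumed above level);
# returns the interpolated sample offset from x[1], or NA.
crossing_time <- function(x, level) {
  below <- which(x < level)
  if (length(below) == 0L) {
    return(NA_real_)
  }
  j <- below[1]
  if (j == 1L) {
    return(0)
  }
  # linear interpolation between samples j-1 (above) and j (below)
  (j - 2L) + (x[j - 1L] - level) / (x[j - 1L] - x[j])
}

#' Empirical cumulative distribution
#'
#' Right-continuous empirical CDF as ordered (value, cumulative
#' probability) pairs, as used for the per-group cumulative probability
#' curves of interevent interval and amplitude.
#'
#' @param values Numeric vector (at least one value).
#' @return A data frame with columns `value` and `cumprob`; the final
#'   probability is 1.
#' @export
#' @examples
#' cumulative_distribution(c(2, 1, 2))
cumulative_distribution <- function(values) {
  if (!is.numeric(values) || length(values) == 0L) {
    stop("`values` must contain at least one number", call. = FALSE)
  }
  v <- sort(unique(values))
  data.frame(value = v, cumprob = stats::ecdf(values)(v))
}

#' Summarize one cell's events
#'
#' Applies every per-cell metric to a detected event table: frequency,
#' backward intervals, eligibility-filtered amplitudes, the isolated-event
#' average and its 80-20% decay time.
#'
#' @param events A `psc_events` data frame ordered by peak time.
#' @param trace The [psc_trace()] the events came from (needed for the
#'   waveform average; may be `NULL` to skip it).
#' @param duration_s Recording duration; defaults to the trace duration.
#' @param config A [metric_config()].
#' @return A list of class `cell_event_summary` with fields `n_events`,
#'   `frequency_hz`, `intervals_s`, `eligible_amplitudes_pa`,
#'   `mean_interval_s`, `mean_amplitude_pa`, `average_event_waveform`,
#'   `decay_time_80_20_ms`. Interval and amplitude means are `NA` when no
#'   qualifying events exist; the waveform is `NULL` when no isolated
#'   events exist.
#' @export
summarize_cell <- function(events, trace = NULL, duration_s = NULL,
                           config = metric_config()) {
  if (is.null(duration_s)) {
    if (is.null(trace)) {
      stop("provide `duration_s` when no trace is given", call. = FALSE)
    }
    duration_s <- trace$duration_s
  }
  ints <- interevent_intervals(events)
  amps <- eligible_amplitudes(events, 0, config)
  wf <- if (!is.null(trace)) {
    isolated_event_average(events, trace, config)
  } else {
    NULL
  }
  decay <- if (!is.null(wf)) {
    tryCatch(decay_time_80_20(wf), error = function(e) NA_real_)
  } else {
    NA_real_
  }
  structure(
    list(
      n_events = nrow(events),
      frequency_hz = psc_frequency(events, duration_s),
      intervals_s = ints,
      eligible_amplitudes_pa = amps,
      mean_interval_s = if (length(ints)) mean(ints) else NA_real_,
      mean_amplitude_pa = if (length(amps)) mean(amps) else NA_real_,
      average_event_waveform = wf,
      decay_time_80_20_ms = decay
    ),
    class = "cell_event_summary"
  )
}

#' @export
print.cell_event_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<cell_event_summary> %d events, %.3f Hz; mean interval %s s; ",
           "mean amplitude %s pA; decay 80-20%% %s ms\n"),
    x$n_events, x$frequency_hz,
    formatC(x$mean_interval_s, digits = 3, format = "fg"),
    formatC(x$mean_amplitude_pa, digits = 3, format = "fg"),
    formatC(x$decay_time_80_20_ms, digits = 3, format = "fg")
  ))
  invisible(x)
}
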