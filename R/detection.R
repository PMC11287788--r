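# PSC event detection and passive-property estimation.

#' Detection configuration
#'
#' Parameters of the automated PSC detector. The defaults mirror common
#' practice for these recordings: a 9-point boxcar ("Box 9") smoother, a
#' detection threshold of 4 robust noise SDs, a 10 ms pre-event baseline
#' window and a 5 ms minimum peak separation.
#'
#' @param smooth_window_points Odd boxcar width in samples (>= 1).
#' @param threshold_mads Detection threshold in units of the median absolute
#'   deviation (MAD, scaled to SD) of the smoothed derivative; the same
#'   multiplier gates the amplitude plausibility filter (> 0).
#' @param baseline_window_ms Pre-event window over which the baseline is
#'   taken as the median (> 0).
#' @param min_peak_separation_ms Minimum separation between retained peaks;
#'   of two closer peaks the larger is kept (> 0).
#' @param decay_check_ms Window after the peak within which the trace must
#'   return at least halfway to baseline for the event to be plausible.
#' @param polarity `"positive"` or `"negative"` going events.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(smooth_window_points = 9, threshold_mads = 4,
                             baseline_window_ms = 10,
                             min_peak_separation_ms = 5,
                             decay_check_ms = 150,
                             polarity = c("positive", "negative")) {
  check_scalar(smooth_window_points, "smooth_window_points", positive = TRUE,
               integerish = TRUE)
  if (smooth_window_points %% 2 == 0) {
    stop("`smooth_window_points` must be odd", call. = FALSE)
  }
  check_scalar(threshold_mads, "threshold_mads", positive = TRUE)
  check_scalar(baseline_window_ms, "baseline_window_ms", positive = TRUE)
  check_scalar(min_peak_separation_ms, "min_peak_separation_ms",
               positive = TRUE)
  check_scalar(decay_check_ms, "decay_check_ms", positive = TRUE)
  structure(
    list(
      smooth_window_points = as.integer(smooth_window_points),
      threshold_mads = threshold_mads,
      baseline_window_ms = baseline_window_ms,
      min_peak_separation_ms = min_peak_separation_ms,
      decay_check_ms = decay_check_ms,
      polarity = match.arg(polarity)
    ),
    class = "detection_config"
  )
}

# Centered boxcar smoother; edges keep the raw samples.
boxcar_smooth <- function(x, w) {
  if (w <= 1L) {
    return(x)
  }
  s <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  na <- is.na(s)
  s[na] <- x[na]
  s
}

#' Detect postsynaptic currents in a trace
#'
#' Automated stand-in for interactive event curation. The trace is boxcar
#' smoothed, the noise scale of its first difference is estimated by the
#' (SD-scaled) median absolute deviation, and event onsets are taken where
#' the derivative crosses `threshold_mads` noise SDs in the event
#' direction. Each onset is followed to the subsequent extremum to localize
#' the peak; peaks closer than `min_peak_separation_ms` are merged (largest
#' kept). The baseline is the median of the `baseline_window_ms` window
#' ending at onset and the amplitude is the absolute difference between
#' peak and baseline. Two plausibility filters replace manual confirmation:
#' the amplitude must exceed `threshold_mads` times the raw-noise SD, and
#' the trace must return at least halfway to baseline within
#' `decay_check_ms` of the peak.
#'
#' @param trace A [psc_trace()].
#' @param config A [detection_config()].
#' @return A data frame of class `psc_events`, ordered by peak time, with
#'   columns `peak_time_s`, `baseline_pa`, `peak_pa`, `amplitude_pa`.
#' @export
#' @examples
#' sim <- generate_psc_trace(trace_spec(duration_s = 20, event_rate_hz = 0.5,
#'                                      seed = 11))
#' ev <- detect_events(sim$trace)
#' nrow(ev)
detect_events <- function(trace, config = detection_config()) {
  stopifnot(inherits(trace, "psc_trace"), inherits(config, "detection_config"))
  x <- trace$samples_pa
  fs <- trace$sample_rate_hz
  w <- config$smooth_window_points
  if (length(x) <= w) {
    stop("trace shorter than the smoothing window", call. = FALSE)
  }
  sgn <- if (config$polarity == "positive") 1 else -1
  s <- boxcar_smooth(sgn * x, w)

  # Rise detector: difference of the smoothed trace across one smoothing
  # window, so the two averaged segments do not overlap and an event's
  # rising edge is not diluted into single-sample increments.
  lag <- w
  d <- s[(1L + lag):length(s)] - s[seq_len(length(s) - lag)]
  sigma_d <- stats::mad(d)
  # raw white-noise SD from first differences (robust to the slow signal)
  sigma_noise <- stats::mad(diff(sgn * x)) / sqrt(2)
  if (sigma_d == 0) {
    # noiseless trace: any non-zero rise is signal
    above <- d > 0
  } else {
    above <- d > config$threshold_mads * sigma_d
  }
  if (!any(above)) {
    return(empty_events())
  }

  # run starts of threshold crossings are candidate onsets
  onset_idx <- which(above & !c(FALSE, above[-length(above)]))

  max_look <- max(1L, round(config$decay_check_ms / 1000 * fs))
  min_sep <- max(1L, round(config$min_peak_separation_ms / 1000 * fs))
  bw <- max(1L, round(config$baseline_window_ms / 1000 * fs))
  n <- length(s)
  stall <- max(3L, round(0.001 * fs))  # 1 ms without a new maximum ends rise

  peaks <- integer(0)
  for (i0 in onset_idx) {
    # climb to the local maximum after the crossing, tolerating noise dips
    # shorter than `stall`
    best <- i0
    k <- i0
    lim <- min(n, i0 + max_look)
    while (k < lim) {
      k <- k + 1L
      if (s[k] >= s[best]) {
        best <- k
      } else if (k - best > stall) {
        break
      }
    }
    peaks <- c(peaks, best)
  }
  keep <- !duplicated(peaks)
  peaks <- peaks[keep]
  onsets <- onset_idx[keep]

  # enforce minimum peak separation, keeping the larger excursion
  if (length(peaks) > 1L) {
    ord <- order(peaks)
    peaks <- peaks[ord]
    onsets <- onsets[ord]
    sel <- rep(TRUE, length(peaks))
    last <- 1L
    for (i in seq_along(peaks)[-1]) {
      if (peaks[i] - peaks[last] < min_sep) {
        if (s[peaks[i]] > s[peaks[last]]) {
          sel[last] <- FALSE
          last <- i
        } else {
          sel[i] <- FALSE
        }
      } else {
        last <- i
      }
    }
    peaks <- peaks[sel]
    onsets <- onsets[sel]
  }

  if (length(peaks) == 0L) {
    return(empty_events())
  }

  baseline <- vapply(seq_along(peaks), function(i) {
    lo <- max(1L, onsets[i] - bw)
    hi <- max(1L, onsets[i] - 1L)
    stats::median(s[lo:hi])
  }, numeric(1))
  peak_val <- s[peaks]
  amp <- peak_val - baseline

  # plausibility filter 1: amplitude above the noise floor
  ok <- amp >= config$threshold_mads * sigma_noise & amp > 0
  # plausibility filter 2: decays back toward baseline
  ok <- ok & vapply(seq_along(peaks), function(i) {
    hi <- min(n, peaks[i] + max_look)
    min(s[peaks[i]:hi]) <= baseline[i] + 0.5 * amp[i]
  }, logical(1))

  peaks <- peaks[ok]
  if (length(peaks) == 0L) {
    return(empty_events())
  }
  structure(
    data.frame(
      peak_time_s = (peaks - 1L) / fs,
      baseline_pa = sgn * baseline[ok],
      peak_pa = sgn * peak_val[ok],
      amplitude_pa = abs(amp[ok])
    ),
    class = c("psc_events", "data.frame")
  )
}

empty_events <- function() {
  structure(
    data.frame(
      peak_time_s = numeric(0), baseline_pa = numeric(0),
      peak_pa = numeric(0), amplitude_pa = numeric(0)
    ),
    class = c("psc_events", "data.frame")
  )
}

#' Match detected events to ground truth
#'
#' Greedy one-to-one matching of detected peak times to true peak times
#' within a tolerance, yielding precision and recall for a detection run on
#' simulated data.
#'
#' @param detected_times_s Detected peak times (s).
#' @param true_times_s Ground-truth peak times (s).
#' @param tol_s Matching tolerance (s; default 2 ms).
#' @return A list with `n_matched`, `precision`, `recall` and the matched
#'   index pairs.
#' @export
match_events <- function(detected_times_s, true_times_s, tol_s = 0.002) {
  nd <- length(detected_times_s)
  nt <- length(true_times_s)
  used <- rep(FALSE, nd)
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("true", "detected")))
  for (i in seq_len(nt)) {
    if (nd == 0L) break
    dt <- abs(detected_times_s - true_times_s[i])
    dt[used] <- Inf
    j <- which.min(dt)
    if (length(j) && dt[j] <= tol_s) {
      used[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  m <- nrow(pairs)
  list(
    n_matched = m,
    precision = if (nd > 0) m / nd else NA_real_,
    recall = if (nt > 0) m / nt else NA_real_,
    pairs = pairs
  )
}

#' Estimate passive properties from membrane-test steps
#'
#' Averages the repeated responses to a small voltage step (study protocol:
#' 16 hyperpolarizing 5 mV, 20 ms steps at 100 kHz) and estimates, using
#' deflection magnitudes throughout: series resistance from the peak
#' capacitive transient (`Rs = dV / I_peak`), input resistance from the
#' steady-state deflection (`Rin = dV / I_ss`), capacitance from the charge
#' of the transient above steady state divided by the step
#' (`C = integral(I - I_ss) dt / dV`), and holding current as the pre-step
#' baseline mean.
#'
#' @param step_responses A numeric matrix with one column per step
#'   repetition (as from [generate_membrane_test()]), or a list of equal
#'   length numeric vectors.
#' @param step_mv Step amplitude in mV (sign irrelevant; magnitude used).
#' @param sample_rate_hz Sampling rate of the segments (Hz).
#' @param step_onset_s Time of step onset within each segment (s).
#' @param step_dur_s Step duration (s).
#' @return A list of class `passive_properties` with `capacitance_pf`,
#'   `input_resistance_gohm`, `series_resistance_mohm`,
#'   `holding_current_pa`.
#' @export
#' @examples
#' mt <- generate_membrane_test(noise_sd_pa = 1, seed = 2)
#' compute_passive_properties(mt$segments, step_mv = -5,
#'                            sample_rate_hz = mt$sample_rate_hz,
#'                            step_onset_s = mt$step_onset_s,
#'                            step_dur_s = mt$step_dur_s)
compute_passive_properties <- function(step_responses, step_mv,
                                       sample_rate_hz, step_onset_s,
                                       step_dur_s) {
  if (is.list(step_responses)) {
    step_responses <- do.call(cbind, step_responses)
  }
  if (!is.matrix(step_responses) || nrow(step_responses) < 2L) {
    stop("`step_responses` must contain at least one segment", call. = FALSE)
  }
  check_scalar(step_mv, "step_mv")
  check_scalar(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  avg <- rowMeans(step_responses)
  dt <- 1 / sample_rate_hz
  i_on <- round(step_onset_s / dt)
  i_off <- min(length(avg), i_on + round(step_dur_s / dt))
  if (i_on < 2L || i_off <= i_on + 4L) {
    stop("segments must contain a pre-step baseline and the full step",
         call. = FALSE)
  }
  holding <- mean(avg[seq_len(i_on)])
  step_idx <- (i_on + 1L):i_off
  defl <- abs(avg[step_idx] - holding)
  # steady state over the last quarter of the step
  ss_idx <- step_idx[seq(floor(length(step_idx) * 0.75) + 1L,
                         length(step_idx))]
  i_ss <- mean(abs(avg[ss_idx] - holding))
  i_peak <- max(defl)
  noise_sd <- stats::sd(avg[seq_len(i_on)])
  if (i_peak <= 5 * noise_sd || i_ss <= 0 || i_peak <= 0) {
    stop("step deflection not discernible above noise", call. = FALSE)
  }
  dv <- abs(step_mv)
  # mV / pA = GOhm
  rs_gohm <- dv / i_peak
  rin_gohm <- dv / i_ss
  charge_pa_s <- sum(pmax(defl - i_ss, 0)) * dt
  c_pf <- 1000 * charge_pa_s / dv
  structure(
    list(
      capacitance_pf = c_pf,
      input_resistance_gohm = rin_gohm,
      series_resistance_mohm = rs_gohm * 1000,
      holding_current_pa = holding
    ),
    class = "passive_properties"
  )
}

#' @export
print.passive_properties <- function(x, ...) {
  cat(sprintf(
    paste0("<passive_properties> C = %.1f pF, Rin = %.2f GOhm, ",
           "Rs = %.1f MOhm, holding = %.1f pA\n"),
    x$capacitance_pf, x$input_resistance_gohm, x$series_resistance_mohm,
    x$holding_current_pa
  ))
  invisible(x)
}

#' Write detected events to CSV
#'
#' @param events A `psc_events` data frame from [detect_events()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}
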