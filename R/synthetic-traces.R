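# Synthetic voltage-clamp traces with ground-truth synaptic events.

#' Specification for a synthetic PSC trace
#'
#' Parameters of a simulated whole-cell voltage-clamp current record:
#' Poisson-timed postsynaptic currents (PSCs) with difference-of-exponentials
#' kinetics and log-normal amplitudes, superposed on a constant holding
#' current with additive white Gaussian noise. Defaults emulate a 2-4 min
#' GABAergic PSC series acquired at 10 kHz from a cell held at -65 mV:
#' event rates of order 0.1-2 Hz and amplitudes of order 10-50 pA are
#' typical for these recordings.
#'
#' @param duration_s Recording duration in seconds (> 0).
#' @param sample_rate_hz Sampling rate in Hz (> 0).
#' @param event_rate_hz Mean event rate of the homogeneous Poisson process
#'   (>= 0).
#' @param amplitude_mean_pa Mean PSC amplitude in pA (> 0).
#' @param amplitude_cv Coefficient of variation of the log-normal amplitude
#'   law (>= 0).
#' @param rise_tau_ms,decay_tau_ms Rise and decay time constants (ms, > 0)
#'   of the kinetic template `(1 - exp(-t/tau_rise)) * exp(-t/tau_decay)`.
#' @param noise_sd_pa Standard deviation of the additive Gaussian noise (pA,
#'   >= 0).
#' @param baseline_pa Holding-current baseline in pA.
#' @param lowpass_hz Optional low-pass cutoff (Hz) mimicking the acquisition
#'   filter; `NA` (default) disables filtering. Requires the \pkg{signal}
#'   package when set.
#' @param seed Integer seed; all randomness of [generate_psc_trace()] flows
#'   from it.
#' @return An object of class `trace_spec`.
#' @seealso [generate_psc_trace()]
#' @export
#' @examples
#' trace_spec(duration_s = 60, event_rate_hz = 1, seed = 42)
trace_spec <- function(duration_s = 240, sample_rate_hz = 10000,
                       event_rate_hz = 0.5, amplitude_mean_pa = 30,
                       amplitude_cv = 0.4, rise_tau_ms = 1,
                       decay_tau_ms = 15, noise_sd_pa = 3,
                       baseline_pa = -20, lowpass_hz = NA, seed = 1L) {
  check_scalar(duration_s, "duration_s", positive = TRUE)
  check_scalar(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  check_scalar(event_rate_hz, "event_rate_hz", nonnegative = TRUE)
  check_scalar(amplitude_mean_pa, "amplitude_mean_pa", positive = TRUE)
  check_scalar(amplitude_cv, "amplitude_cv", nonnegative = TRUE)
  check_scalar(rise_tau_ms, "rise_tau_ms", positive = TRUE)
  check_scalar(decay_tau_ms, "decay_tau_ms", positive = TRUE)
  check_scalar(noise_sd_pa, "noise_sd_pa", nonnegative = TRUE)
  check_scalar(baseline_pa, "baseline_pa")
  structure(
    list(
      duration_s = duration_s, sample_rate_hz = sample_rate_hz,
      event_rate_hz = event_rate_hz, amplitude_mean_pa = amplitude_mean_pa,
      amplitude_cv = amplitude_cv, rise_tau_ms = rise_tau_ms,
      decay_tau_ms = decay_tau_ms, noise_sd_pa = noise_sd_pa,
      baseline_pa = baseline_pa, lowpass_hz = lowpass_hz,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "trace_spec"
  )
}

#' Current trace container
#'
#' A sampled current record from one voltage-clamped cell.
#'
#' @param samples_pa Numeric vector of current samples (pA), at least one.
#' @param sample_rate_hz Sampling rate in Hz (> 0).
#' @param holding_mv Command potential in mV (study recordings: -65).
#' @return An object of class `psc_trace` with fields `samples_pa`,
#'   `sample_rate_hz`, `holding_mv` and derived `duration_s`.
#' @export
psc_trace <- function(samples_pa, sample_rate_hz, holding_mv = -65) {
  if (!is.numeric(samples_pa) || length(samples_pa) < 1L) {
    stop("`samples_pa` must contain at least one sample", call. = FALSE)
  }
  check_scalar(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  structure(
    list(
      samples_pa = as.numeric(samples_pa),
      sample_rate_hz = sample_rate_hz,
      holding_mv = holding_mv,
      duration_s = length(samples_pa) / sample_rate_hz
    ),
    class = "psc_trace"
  )
}

#' @export
print.psc_trace <- function(x, ...) {
  cat(sprintf(
    "<psc_trace> %.1f s at %g kHz (%d samples), held at %g mV\n",
    x$duration_s, x$sample_rate_hz / 1000, length(x$samples_pa), x$holding_mv
  ))
  invisible(x)
}

# Peak-normalized kinetic template evaluated at times t (seconds, from event
# onset). Peak occurs at t* = tau_r * log(1 + tau_d/tau_r).
psc_template <- function(t_s, rise_tau_ms, decay_tau_ms) {
  tr <- rise_tau_ms / 1000
  td <- decay_tau_ms / 1000
  w <- (1 - exp(-t_s / tr)) * exp(-t_s / td)
  w[t_s < 0] <- 0
  t_pk <- tr * log(1 + td / tr)
  w_pk <- (1 - exp(-t_pk / tr)) * exp(-t_pk / td)
  w / w_pk
}

# Time from template onset to peak, in seconds.
psc_template_peak_offset <- function(rise_tau_ms, decay_tau_ms) {
  (rise_tau_ms / 1000) * log(1 + decay_tau_ms / rise_tau_ms)
}

#' Simulate a PSC trace with ground truth
#'
#' Generates a current trace from a [trace_spec()]: event onsets follow a
#' homogeneous Poisson process, each event is a peak-normalized
#' difference-of-exponentials template scaled by a log-normal amplitude,
#' overlapping events superpose linearly, and white Gaussian noise is added
#' to the holding-current baseline. Events are positive-going excursions;
#' amplitudes are reported as absolute values.
#'
#' @param spec A [trace_spec()].
#' @return A list with components `trace` (a [psc_trace()]) and `truth`, a
#'   data frame with one row per event: `onset_time_s` (the Poisson onset),
#'   `peak_time_s` (onset plus the analytic template peak offset) and
#'   `amplitude_pa`.
#' @export
#' @examples
#' out <- generate_psc_trace(trace_spec(duration_s = 10, event_rate_hz = 1,
#'                                      seed = 7))
#' nrow(out$truth)
generate_psc_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  n <- round(spec$duration_s * spec$sample_rate_hz)
  dt <- 1 / spec$sample_rate_hz
  with_seed(spec$seed, {
    n_ev <- stats::rpois(1L, spec$event_rate_hz * spec$duration_s)
    onsets <- sort(stats::runif(n_ev, 0, spec$duration_s))
    if (spec$amplitude_cv > 0) {
      sdlog <- sqrt(log(1 + spec$amplitude_cv^2))
      meanlog <- log(spec$amplitude_mean_pa) - sdlog^2 / 2
      amps <- stats::rlnorm(n_ev, meanlog, sdlog)
    } else {
      amps <- rep(spec$amplitude_mean_pa, n_ev)
    }
    x <- rep(spec$baseline_pa, n)
    if (n_ev > 0) {
      # Template support: 8 decay constants is < 0.1% residual amplitude.
      len <- min(n, ceiling(8 * spec$decay_tau_ms / 1000 / dt))
      tmpl_t <- (seq_len(len) - 1L) * dt
      for (i in seq_len(n_ev)) {
        i0 <- floor(onsets[i] / dt) + 1L
        idx <- i0:min(n, i0 + len - 1L)
        # offset of first affected sample relative to the exact onset time
        off <- (i0 - 1L) * dt - onsets[i]
        x[idx] <- x[idx] +
          amps[i] * psc_template(tmpl_t[seq_along(idx)] + off,
                                 spec$rise_tau_ms, spec$decay_tau_ms)
      }
    }
    if (spec$noise_sd_pa > 0) {
      x <- x + stats::rnorm(n, 0, spec$noise_sd_pa)
    }
    if (!is.na(spec$lowpass_hz)) {
      x <- lowpass_trace(x, spec$sample_rate_hz, spec$lowpass_hz)
    }
    truth <- data.frame(
      onset_time_s = onsets,
      peak_time_s = onsets +
        psc_template_peak_offset(spec$rise_tau_ms, spec$decay_tau_ms),
      amplitude_pa = amps
    )
    list(trace = psc_trace(x, spec$sample_rate_hz), truth = truth)
  })
}

# Zero-phase Butterworth low-pass mimicking the acquisition filter.
lowpass_trace <- function(x, sample_rate_hz, cutoff_hz) {
  nyq <- sample_rate_hz / 2
  if (cutoff_hz >= nyq) {
    return(x)
  }
  if (!requireNamespace("signal", quietly = TRUE)) {
    stop("the `signal` package is required for low-pass filtering",
         call. = FALSE)
  }
  bf <- signal::butter(2, cutoff_hz / nyq, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Simulate an averaged membrane-test step response
#'
#' Analytic single-compartment response to a hyperpolarizing voltage step
#' applied through a series (access) resistance: an instantaneous capacitive
#' transient of magnitude `step / Rs` relaxing with time constant
#' `C * Rs * Rm / (Rs + Rm)` to the steady state `step / (Rs + Rm)`, plus
#' optional Gaussian noise. Used for testing [compute_passive_properties()]
#' and for generating recording-quality records in the synthetic cohort.
#' Hyperpolarizing steps give negative current deflections.
#'
#' @param step_mv Voltage step in mV (study protocol: -5).
#' @param rs_mohm Series resistance (MOhm).
#' @param rin_gohm Membrane (input) resistance (GOhm).
#' @param c_pf Cell capacitance (pF).
#' @param holding_pa Pre-step holding current (pA).
#' @param pre_ms,step_ms Baseline and step durations (ms; study: 20 ms step).
#' @param sample_rate_hz Sampling rate (Hz; study: 100 kHz).
#' @param noise_sd_pa Additive noise SD (pA).
#' @param n_steps Number of repeated step segments to return (study: 16).
#' @param seed Integer seed.
#' @return A list with `segments` (matrix, one column per repetition),
#'   `sample_rate_hz`, `step_onset_s` and `step_dur_s`.
#' @export
generate_membrane_test <- function(step_mv = -5, rs_mohm = 20, rin_gohm = 1,
                                   c_pf = 20, holding_pa = -20, pre_ms = 10,
                                   step_ms = 20, sample_rate_hz = 1e5,
                                   noise_sd_pa = 0, n_steps = 16,
                                   seed = 1L) {
  check_scalar(rs_mohm, "rs_mohm", positive = TRUE)
  check_scalar(rin_gohm, "rin_gohm", positive = TRUE)
  check_scalar(c_pf, "c_pf", positive = TRUE)
  dt <- 1 / sample_rate_hz
  n_pre <- round(pre_ms / 1000 / dt)
  n_step <- round(step_ms / 1000 / dt)
  rs <- rs_mohm * 1e6
  rm <- rin_gohm * 1e9
  cc <- c_pf * 1e-12
  dv <- step_mv * 1e-3
  tau <- cc * rs * rm / (rs + rm)
  t_step <- (seq_len(n_step) - 0.5) * dt  # mid-sample times within the step
  i_ss <- dv / (rs + rm)
  i_t <- i_ss + (dv / rs - i_ss) * exp(-t_step / tau)
  ideal <- c(rep(0, n_pre), i_t) * 1e12 + holding_pa
  with_seed(seed, {
    segs <- vapply(seq_len(n_steps), function(i) {
      ideal + if (noise_sd_pa > 0) {
        stats::rnorm(length(ideal), 0, noise_sd_pa)
      } else {
        0
      }
    }, numeric(length(ideal)))
    list(
      segments = segs,
      sample_rate_hz = sample_rate_hz,
      step_onset_s = n_pre * dt,
      step_dur_s = n_step * dt
    )
  })
}

#' Read and write current traces
#'
#' Traces are exchanged as two-column text: either CSV with header
#' `time_s,current_pa` or tab-delimited ATF-style text (a two-line header
#' followed by time/current columns), the common export formats of
#' acquisition software.
#'
#' @param trace A [psc_trace()].
#' @param path File path.
#' @param format `"csv"` or `"atf"`.
#' @param holding_mv Holding potential to record in the returned trace.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   a [psc_trace()] (the sampling rate is inferred from the time column).
#' @export
write_trace <- function(trace, path, format = c("csv", "atf")) {
  stopifnot(inherits(trace, "psc_trace"))
  format <- match.arg(format)
  t_s <- (seq_along(trace$samples_pa) - 1L) / trace$sample_rate_hz
  if (format == "csv") {
    utils::write.csv(
      data.frame(time_s = t_s, current_pa = trace$samples_pa),
      path, row.names = FALSE
    )
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ATF\t1.0", "0\t2", "\"Time (s)\"\t\"Current (pA)\""), con)
    utils::write.table(
      data.frame(t_s, trace$samples_pa), con,
      sep = "\t", row.names = FALSE, col.names = FALSE
    )
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, format = c("csv", "atf"), holding_mv = -65) {
  format <- match.arg(format)
  df <- if (format == "csv") {
    utils::read.csv(path)
  } else {
    utils::read.table(path, sep = "\t", skip = 3)
  }
  if (ncol(df) < 2L || nrow(df) < 2L) {
    stop("trace file must have two columns (time, current)", call. = FALSE)
  }
  dt <- stats::median(diff(df[[1]]))
  psc_trace(df[[2]], sample_rate_hz = 1 / dt, holding_mv = holding_mv)
}
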