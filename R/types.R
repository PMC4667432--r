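# Core containers. Plain S3 lists with validating constructors, in the style
# of base-R time-series objects: cheap to build in simulation loops, printed
# compactly, and with invariants enforced at construction rather than at use.

#' Whole-cell current trace
#'
#' A uniformly sampled current recording. Samples keep their physical sign
#' (EPSCs recorded at -60 mV are negative-going, inward current); analysis
#' functions report magnitudes.
#'
#' @param samples numeric vector of current in pA; all finite, length >= 2.
#' @param sampling_rate sampling rate in Hz, > 0.
#' @param t0 time of the first sample in seconds.
#' @param channel_label free-text channel label.
#'
#' @return An object of class `"trace"`: a list with fields `samples`,
#'   `sampling_rate`, `t0`, `channel_label`.
#' @examples
#' tr <- trace(c(0, -10, 0), sampling_rate = 10000)
#' trace_duration(tr)
#' @export
trace <- function(samples, sampling_rate, t0 = 0, channel_label = "Im") {
  samples <- as.numeric(samples)
  if (length(samples) < 2) {
    rrp_abort("a trace needs at least 2 samples", "rrpool_parameter_error")
  }
  if (!all(is.finite(samples))) {
    rrp_abort("trace samples must all be finite", "rrpool_parameter_error")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    rrp_abort("sampling_rate must be a single positive number (Hz)",
              "rrpool_parameter_error")
  }
  structure(
    list(samples = samples,
         sampling_rate = as.numeric(sampling_rate),
         t0 = as.numeric(t0),
         channel_label = as.character(channel_label)[1]),
    class = "trace")
}

#' Sample times of a trace
#' @param x a [trace()].
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$t0 + (seq_along(x$samples) - 1) / x$sampling_rate
}

#' Trace duration in seconds
#' @param x a [trace()].
#' @return duration spanned by the samples, in seconds.
#' @export
trace_duration <- function(x) {
  stopifnot(inherits(x, "trace"))
  (length(x$samples) - 1) / x$sampling_rate
}

# Nearest sample index for time t (clamped into range).
trace_index <- function(x, t) {
  i <- round((t - x$t0) * x$sampling_rate) + 1
  pmin(pmax(i, 1L), length(x$samples))
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ %g Hz (%.4g s), channel '%s'\n",
              length(x$samples), x$sampling_rate, trace_duration(x),
              x$channel_label))
  cat(sprintf("  current range [%.4g, %.4g] pA, t0 = %g s\n",
              min(x$samples), max(x$samples), x$t0))
  invisible(x)
}

#' Stimulus train
#'
#' Strictly increasing stimulus times. The nominal frequency is inferred
#' when the spacing is uniform (within 0.1% relative tolerance).
#'
#' @param times stimulus times in seconds, strictly increasing.
#' @param nominal_frequency optional nominal stimulation frequency in Hz;
#'   inferred from uniform spacing when `NULL`.
#' @return An object of class `"stimulus_train"` with fields `times` and
#'   `nominal_frequency` (possibly `NA`).
#' @examples
#' stimulus_train(seq(0.1, by = 0.05, length.out = 60))
#' @export
stimulus_train <- function(times, nominal_frequency = NULL) {
  times <- as.numeric(times)
  if (length(times) == 0) {
    rrp_abort("stimulus train is empty", "rrpool_validation_error")
  }
  if (!all(is.finite(times))) {
    rrp_abort("stimulus times must be finite", "rrpool_validation_error")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    rrp_abort("stimulus times must be strictly increasing",
              "rrpool_validation_error")
  }
  if (is.null(nominal_frequency)) {
    nominal_frequency <- NA_real_
    if (length(times) >= 2) {
      d <- diff(times)
      if (max(abs(d - mean(d))) <= 1e-3 * mean(d)) {
        nominal_frequency <- 1 / mean(d)
      }
    }
  }
  structure(list(times = times,
                 nominal_frequency = as.numeric(nominal_frequency)),
            class = "stimulus_train")
}

#' Regularly spaced stimulus train
#'
#' @param n number of stimuli.
#' @param rate_hz stimulation frequency in Hz.
#' @param t_start time of the first stimulus in seconds.
#' @return a [stimulus_train()].
#' @export
regular_train <- function(n, rate_hz, t_start = 0.1) {
  stimulus_train(t_start + (seq_len(n) - 1) / rate_hz,
                 nominal_frequency = rate_hz)
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("<stimulus_train> %d stimuli over [%.4g, %.4g] s",
              length(x$times), min(x$times), max(x$times)))
  if (is.finite(x$nominal_frequency)) {
    cat(sprintf(", nominal %g Hz", x$nominal_frequency))
  }
  cat("\n")
  invisible(x)
}

#' Per-stimulus EPSC series from a train
#'
#' Holds the baseline-corrected charge r(i) and peak amplitude of each EPSC
#' in a stimulus train, plus the steady-state charge r(inf) defined as the
#' mean of the last 10 entries (present only when n >= 10).
#'
#' @param r per-stimulus charge magnitudes in pC, length >= 2, all >= 0.
#' @param peaks per-stimulus peak amplitude magnitudes in pA.
#' @param dt interstimulus interval in seconds, > 0.
#' @param baseline_refs per-stimulus pre-artefact reference current in pA
#'   (spill-over correction baselines); defaults to zeros.
#' @return An object of class `"epsc_series"` with fields `r`, `peaks`,
#'   `dt`, `r_inf` (mean of last 10 charges, or `NA` when n < 10) and
#'   `baseline_refs`.
#' @examples
#' s <- epsc_series(r = c(4, 3, 2.5, 2.2), peaks = c(400, 300, 250, 220),
#'                  dt = 0.05)
#' cumulative_charge(s)
#' @export
epsc_series <- function(r, peaks, dt, baseline_refs = NULL) {
  r <- as.numeric(r)
  peaks <- as.numeric(peaks)
  n <- length(r)
  if (n < 2) rrp_abort("an EPSC series needs n >= 2", "rrpool_parameter_error")
  if (length(peaks) != n) {
    rrp_abort("r and peaks must have equal length", "rrpool_parameter_error")
  }
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    rrp_abort("dt must be a single positive number (s)",
              "rrpool_parameter_error")
  }
  if (any(!is.finite(r)) || any(r < 0)) {
    rrp_abort("charges r must be finite non-negative magnitudes (pC)",
              "rrpool_parameter_error")
  }
  if (is.null(baseline_refs)) baseline_refs <- numeric(n)
  if (length(baseline_refs) != n) {
    rrp_abort("baseline_refs must match length of r", "rrpool_parameter_error")
  }
  r_inf <- if (n >= 10) mean(r[(n - 9):n]) else NA_real_
  structure(list(r = r, peaks = peaks, dt = dt, r_inf = r_inf,
                 baseline_refs = as.numeric(baseline_refs)),
            class = "epsc_series")
}

#' @export
print.epsc_series <- function(x, ...) {
  cat(sprintf("<epsc_series> n = %d, dt = %g ms\n", length(x$r), x$dt * 1000))
  cat(sprintf("  r(1) = %.4g pC, r(inf) = %s pC, peak(1) = %.4g pA\n",
              x$r[1], ifelse(is.na(x$r_inf), "NA", sprintf("%.4g", x$r_inf)),
              x$peaks[1]))
  invisible(x)
}

#' Depletion-refill pool model parameters
#'
#' Parameters of the first-order vesicle pool model: the pool capacity
#' (RRP, measured as charge), the fusion efficiency fe (fraction of the
#' available pool released per stimulus) and the refill rate constant
#' alpha (first-order recovery toward capacity between stimuli). Optional
#' facilitation fields extend the model to a facilitation-depression form
#' in which the release fraction is transiently augmented by each stimulus.
#'
#' @param rrp_charge pool capacity in pC, > 0.
#' @param fe fusion efficiency, in (0, 1].
#' @param alpha refill rate constant in 1/s, >= 0.
#' @param facil_increment facilitation increment U_f in \[0, 1), or `NULL`
#'   for the depletion-only model.
#' @param facil_tau facilitation decay time constant in seconds; required
#'   when `facil_increment` is given.
#' @return An object of class `"pool_params"`.
#' @examples
#' pool_params(rrp_charge = 16.3, fe = 0.3, alpha = 2)
#' @export
pool_params <- function(rrp_charge, fe, alpha,
                        facil_increment = NULL, facil_tau = NULL) {
  if (!is.finite(rrp_charge) || rrp_charge <= 0) {
    rrp_abort("rrp_charge must be > 0 (pC)", "rrpool_parameter_error")
  }
  if (!is.finite(fe) || fe <= 0 || fe > 1) {
    rrp_abort("fe must lie in (0, 1]", "rrpool_parameter_error")
  }
  if (!is.finite(alpha) || alpha < 0) {
    rrp_abort("alpha must be >= 0 (1/s)", "rrpool_parameter_error")
  }
  if (!is.null(facil_increment)) {
    if (!is.finite(facil_increment) || facil_increment < 0 ||
        facil_increment >= 1) {
      rrp_abort("facil_increment must lie in [0, 1)", "rrpool_parameter_error")
    }
    if (is.null(facil_tau) || !is.finite(facil_tau) || facil_tau <= 0) {
      rrp_abort("facil_tau (s, > 0) is required with facil_increment",
                "rrpool_parameter_error")
    }
  }
  structure(list(rrp_charge = as.numeric(rrp_charge), fe = as.numeric(fe),
                 alpha = as.numeric(alpha),
                 facil_increment = if (is.null(facil_increment)) NULL
                                   else as.numeric(facil_increment),
                 facil_tau = if (is.null(facil_tau)) NULL
                             else as.numeric(facil_tau)),
            class = "pool_params")
}

#' @export
print.pool_params <- function(x, ...) {
  cat(sprintf("<pool_params> RRP = %.4g pC, fe = %.4g, alpha = %.4g /s",
              x$rrp_charge, x$fe, x$alpha))
  if (!is.null(x$facil_increment)) {
    cat(sprintf(", U_f = %.3g, tau_f = %g ms",
                x$facil_increment, x$facil_tau * 1000))
  }
  cat("\n")
  invisible(x)
}
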