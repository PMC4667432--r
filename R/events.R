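# Miniature-event detection and per-stimulus charge extraction.

# Robust noise SD: MAD of first differences, scaled back to sample units.
# First-differencing whitens slow baseline drift and removes the synaptic
# events themselves from the bulk of the distribution.
noise_sd_estimate <- function(samples) {
  stats::mad(diff(samples)) / sqrt(2)
}

#' Detect miniature synaptic events
#'
#' Detects negative-going miniature events. With a `kernel_hint`, detection
#' is by matched filtering: the trace is correlated with the unit-peak
#' kernel, yielding per-sample amplitude estimates whose noise SD is
#' `sigma / sqrt(sum(u^2))`; candidate onsets are local maxima of that
#' score above `threshold_sd` score-SDs, separated by at least
#' `min_separation`. Without a hint, a short boxcar-smoothed amplitude
#' threshold is used. The noise SD `sigma` is estimated from the median
#' absolute deviation of the differenced trace, which is robust to event
#' contamination.
#'
#' For each event the baseline is the mean current over 1 ms immediately
#' before onset; the amplitude is the baseline-subtracted peak magnitude
#' (ties broken by the earliest sample) and the charge is the integral of
#' the baseline-subtracted segment over a window of 5 decay constants.
#'
#' @param trace a [trace()].
#' @param threshold_sd detection threshold in units of the score noise SD,
#'   > 0 (default 5).
#' @param min_separation minimum separation between detected onsets, s.
#' @param kernel_hint optional [make_kernel()] template for matched
#'   filtering; also supplies the decay constant for the charge window.
#' @return a `data.frame` with one row per event, sorted by onset:
#'   `onset` (s), `peak_amplitude` (pA, magnitude), `charge` (fC),
#'   `decay_tau` (s; the hint's decay or a per-event estimate).
#' @export
detect_mepscs <- function(trace, threshold_sd = 5, min_separation = 0.005,
                          kernel_hint = NULL) {
  stopifnot(inherits(trace, "trace"))
  if (!is.finite(threshold_sd) || threshold_sd <= 0) {
    rrp_abort("threshold_sd must be > 0", "rrpool_parameter_error")
  }
  fs <- trace$sampling_rate
  x <- trace$samples
  n <- length(x)
  if (!is.null(kernel_hint)) {
    stopifnot(inherits(kernel_hint, "event_kernel"))
    if (n < 10 * kernel_hint$tau_decay * fs) {
      rrp_abort("trace shorter than 10 kernel decay constants",
                "rrpool_parameter_error")
    }
  }
  y <- -(x - stats::median(x))      # events positive-going
  sigma <- noise_sd_estimate(x)
  if (sigma <= 0) sigma <- .Machine$double.eps

  if (!is.null(kernel_hint)) {
    tmpl_len <- max(2, round(5 * kernel_hint$tau_decay * fs))
    u <- kernel_eval(kernel_hint, (seq_len(tmpl_len) - 1) / fs) /
      kernel_hint$amplitude
    # score_o = sum_j y[o + j - 1] u_j / sum(u^2): least-squares amplitude
    # of a unit-peak template starting at o
    s <- stats::filter(y, rev(u), method = "convolution", sides = 1)
    score <- c(as.numeric(s[tmpl_len:n]) / sum(u^2),
               rep(0, tmpl_len - 1))
    score_sd <- sigma / sqrt(sum(u^2))
    decay_hint <- kernel_hint$tau_decay
  } else {
    k <- max(1, round(5e-4 * fs))   # 0.5 ms boxcar
    sm <- stats::filter(y, rep(1 / k, k), method = "convolution", sides = 1)
    score <- as.numeric(sm)
    score[!is.finite(score)] <- 0
    score_sd <- sigma / sqrt(k)
    decay_hint <- NA_real_
  }
  thr <- threshold_sd * score_sd
  above <- which(score > thr)
  if (length(above) == 0) {
    return(data.frame(onset = numeric(0), peak_amplitude = numeric(0),
                      charge = numeric(0), decay_tau = numeric(0)))
  }
  sep <- max(1, round(min_separation * fs))
  breaks <- which(diff(above) > sep)
  starts <- c(1, breaks + 1)
  ends <- c(breaks, length(above))
  onset_idx <- vapply(seq_along(starts), function(g) {
    run <- above[starts[g]:ends[g]]
    run[which.max(score[run])]   # earliest sample wins ties
  }, integer(1))
  if (is.null(kernel_hint)) {
    # boxcar score peaks near the event peak; step back to the threshold
    # crossing as the onset estimate
    onset_idx <- vapply(seq_along(starts), function(g) above[starts[g]],
                        integer(1))
  }

  base_w <- max(1, round(0.001 * fs))
  rows <- lapply(onset_idx, function(i0) {
    b_idx <- max(1, i0 - base_w):(max(1, i0 - 1))
    baseline <- mean(x[b_idx])
    tau <- decay_hint
    if (is.na(tau)) {
      # crude per-event decay: time from peak to 1/e of peak
      search_end <- min(n, i0 + round(0.05 * fs))
      d0 <- -(x[i0:search_end] - baseline)
      p_rel <- which.max(d0)
      below <- which(d0[p_rel:length(d0)] < d0[p_rel] / exp(1))
      tau <- if (length(below)) (below[1] - 1) / fs else 0.01
      tau <- max(tau, 1 / fs)
    }
    win_end <- min(n, i0 + round(5 * tau * fs))
    d <- -(x[i0:win_end] - baseline)
    peak <- max(d)
    charge_pc <- abs(sum(d)) / fs
    c(onset = trace$t0 + (i0 - 1) / fs, peak_amplitude = peak,
      charge = pc_to_fc(charge_pc), decay_tau = tau)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out[out$peak_amplitude > 0 & out$charge > 0, , drop = FALSE]
}

#' Mean miniature-event amplitude and charge
#'
#' The means define the quantal size used by [quantal_content()].
#'
#' @param events a data.frame from [detect_mepscs()] (columns
#'   `peak_amplitude` in pA and `charge` in fC), with at least one row.
#' @return list with `mean_amplitude` (pA), `mean_charge` (fC) and `n`.
#' @export
mean_mepsc <- function(events) {
  if (is.null(events) || nrow(events) < 1) {
    rrp_abort("no events to average", "rrpool_estimation_error")
  }
  list(mean_amplitude = mean(events$peak_amplitude),
       mean_charge = mean(events$charge),
       n = nrow(events))
}

#' Extract a per-stimulus EPSC series from a train recording
#'
#' Implements spill-over-corrected charge integration: for each stimulus
#' the reference baseline is the mean current over the 1 ms immediately
#' preceding the stimulus time (i.e. before its artefact), so the decaying
#' tail of the previous response is subtracted out. The response window
#' runs from the end of the blanked artefact to the next stimulus (the
#' last stimulus uses `response_window`). Within each window,
#' `r(i) = |integral of (I - baseline_i)|` in pC and `peak(i)` is the
#' maximum baseline-subtracted magnitude.
#'
#' @param trace a [trace()].
#' @param train a [stimulus_train()] whose times lie within the trace.
#' @param blank_window artefact blanking time after each stimulus, s
#'   (default 2 ms); must be shorter than the minimum interstimulus
#'   interval.
#' @param response_window integration window after the last stimulus, s;
#'   defaults to the minimum interstimulus interval.
#' @return an [epsc_series()]; `r_inf` is the mean of the last 10 charges
#'   when the train has at least 10 stimuli.
#' @export
epsc_series_from_train <- function(trace, train, blank_window = 0.002,
                                   response_window = NULL) {
  stopifnot(inherits(trace, "trace"), inherits(train, "stimulus_train"))
  times <- train$times
  n_stim <- length(times)
  if (n_stim < 2) {
    rrp_abort("need at least 2 stimuli", "rrpool_parameter_error")
  }
  t_end <- trace$t0 + trace_duration(trace)
  if (times[1] < trace$t0 || times[n_stim] > t_end) {
    rrp_abort("stimulus times fall outside the trace", "rrpool_parameter_error")
  }
  isi <- diff(times)
  if (blank_window >= min(isi)) {
    rrp_abort("blank_window overlaps the next stimulus",
              "rrpool_parameter_error")
  }
  if (is.null(response_window)) response_window <- min(isi)
  fs <- trace$sampling_rate
  x <- trace$samples
  base_w <- max(1, round(0.001 * fs))
  r <- peaks <- base_refs <- numeric(n_stim)
  for (i in seq_len(n_stim)) {
    i_stim <- trace_index(trace, times[i])
    b_idx <- max(1, i_stim - base_w):max(1, i_stim - 1)
    baseline <- mean(x[b_idx])
    w_start <- times[i] + blank_window
    w_end <- if (i < n_stim) times[i + 1] else times[i] + response_window
    i_hi <- trace_index(trace, min(w_end, t_end))
    if (i < n_stim) i_hi <- i_hi - 1L   # exclude the next stimulus sample
    idx <- trace_index(trace, w_start):i_hi
    d <- x[idx] - baseline
    r[i] <- abs(sum(d)) / fs
    peaks[i] <- max(abs(d))
    base_refs[i] <- baseline
  }
  epsc_series(r = r, peaks = peaks,
              dt = if (length(isi)) stats::median(isi) else response_window,
              baseline_refs = base_refs)
}
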