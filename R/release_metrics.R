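# Paired-pulse ratio, quantal content, MK-801 block kinetics and
# input-output summarization.

#' Paired-pulse ratio
#'
#' PPR is the peak amplitude of the second response divided by that of the
#' first. In depletion-dominated synapses PPR is inversely related to
#' release probability; in the first-order pool model a noiseless pair
#' gives `PPR = 1 - fe * exp(-alpha * dt)`.
#'
#' @param series an [epsc_series()] with n >= 2.
#' @param noise_floor amplitude (pA) below which the first response is
#'   considered indistinguishable from noise and the PPR undefined.
#' @return the paired-pulse ratio (dimensionless).
#' @export
paired_pulse_ratio <- function(series, noise_floor = 0) {
  stopifnot(inherits(series, "epsc_series"))
  if (series$peaks[1] <= noise_floor || series$peaks[1] <= 0) {
    rrp_abort("first response at or below the noise floor; PPR undefined",
              "rrpool_estimation_error")
  }
  series$peaks[2] / series$peaks[1]
}

#' Paired-pulse ratio before and after a conditioning protocol
#'
#' Computes per-trial PPRs for two sets of trials (e.g. the minute before
#' and after high-frequency stimulation) and their difference.
#'
#' @param pre_series list of [epsc_series()] recorded before.
#' @param post_series list of [epsc_series()] recorded after.
#' @param ... passed to [paired_pulse_ratio()].
#' @return list with `mean_pre`, `mean_post` and `difference`
#'   (post minus pre; negative when PPR drops, i.e. release probability
#'   rose).
#' @export
ppr_pre_post <- function(pre_series, post_series, ...) {
  if (length(pre_series) == 0 || length(post_series) == 0) {
    rrp_abort("both trial lists must be non-empty", "rrpool_estimation_error")
  }
  pre <- vapply(pre_series, paired_pulse_ratio, numeric(1), ...)
  post <- vapply(post_series, paired_pulse_ratio, numeric(1), ...)
  list(mean_pre = mean(pre), mean_post = mean(post),
       difference = mean(post) - mean(pre))
}

#' Quantal content of an evoked response
#'
#' The number of quanta per stimulus, estimated either as the ratio of
#' EPSC peak amplitude to mean mEPSC amplitude (`amplitude_ratio`) or as
#' the integrated EPSC charge divided by the integral of the average mEPSC
#' (`charge_ratio`).
#'
#' @param evoked the evoked quantity: peak amplitude in pA for
#'   `amplitude_ratio`, charge in pC for `charge_ratio`.
#' @param mepsc quantal size, as returned by [mean_mepsc()] (fields
#'   `mean_amplitude` in pA, `mean_charge` in fC).
#' @param method estimator variant.
#' @return an object of class `"quantal_estimate"`: list with `m` (quanta
#'   per stimulus, >= 0) and `method`.
#' @examples
#' quantal_content(1.18, list(mean_amplitude = 12, mean_charge = 118),
#'                 method = "charge_ratio")  # m = 10
#' @export
quantal_content <- function(evoked, mepsc,
                            method = c("amplitude_ratio", "charge_ratio")) {
  method <- match.arg(method)
  denom <- switch(method,
                  amplitude_ratio = mepsc$mean_amplitude,
                  charge_ratio = fc_to_pc(mepsc$mean_charge))
  if (is.null(denom) || !is.finite(denom) || denom <= 0) {
    rrp_abort("mean mEPSC quantity must be > 0", "rrpool_estimation_error")
  }
  if (!is.finite(evoked) || evoked < 0) {
    rrp_abort("evoked quantity must be >= 0", "rrpool_parameter_error")
  }
  structure(list(m = evoked / denom, method = method),
            class = "quantal_estimate")
}

#' @export
print.quantal_estimate <- function(x, ...) {
  cat(sprintf("<quantal_estimate> m = %.4g quanta/stimulus (%s)\n",
              x$m, x$method))
  invisible(x)
}

#' Fit the MK-801 use-dependent block time constant
#'
#' Fits a single exponential `A_n = exp(-(n - 1) / tau)` to NMDA-EPSC
#' amplitudes normalized to the first stimulus in the presence of MK-801.
#' The decay time constant tau (in stimulus counts) reports release
#' probability: faster block (smaller tau) means higher release
#' probability. The fit is a weighted least-squares line through the
#' origin on log amplitudes (weights proportional to amplitude, the usual
#' variance stabilization for multiplicative decay) refined by a
#' 1-D nonlinear least-squares minimization on the untransformed scale.
#'
#' @param amplitudes normalized amplitude series; first entry must be 1,
#'   length >= 5. Values are floored at 1e-6 before the log transform.
#' @return An object of class `"mk801_fit"`: list with
#'   `normalized_amplitudes`, `tau` (stimulus counts; `Inf` with
#'   `no_block = TRUE` when the series does not decay), `fit_residual`
#'   (root-mean-square residual) and `no_block`.
#' @examples
#' fit_mk801_block(0.5^(0:19))$tau  # 1 / log(2)
#' @export
fit_mk801_block <- function(amplitudes) {
  a <- as.numeric(amplitudes)
  n <- length(a)
  if (n < 5) rrp_abort("need at least 5 stimuli", "rrpool_parameter_error")
  if (abs(a[1] - 1) > 1e-9) {
    rrp_abort("amplitudes must be normalized to the first stimulus (A_1 = 1)",
              "rrpool_parameter_error")
  }
  z <- seq_len(n) - 1
  af <- pmax(a, 1e-6)
  l <- log(af)
  # weighted LS through the origin: slope = -1/tau
  slope <- sum(af * z * l) / sum(af * z^2)
  if (!is.finite(slope) || slope >= -1e-12) {
    rrp_warn("series does not decay; no measurable block (tau -> Inf)",
             "rrpool_fit_warning")
    return(structure(list(normalized_amplitudes = a, tau = Inf,
                          fit_residual = sqrt(mean((a - 1)^2)),
                          no_block = TRUE),
                     class = "mk801_fit"))
  }
  tau0 <- -1 / slope
  obj <- function(tau) sum((a - exp(-z / tau))^2)
  opt <- stats::optimize(obj, interval = c(tau0 / 10, tau0 * 10))
  tau <- opt$minimum
  resid <- sqrt(opt$objective / n)
  if (mean(diff(a) > 0) > 0.5) {
    rrp_warn("amplitude series is mostly non-decreasing; fit quality is poor",
             "rrpool_fit_warning")
  }
  structure(list(normalized_amplitudes = a, tau = tau, fit_residual = resid,
                 no_block = FALSE),
            class = "mk801_fit")
}

#' @export
print.mk801_fit <- function(x, ...) {
  cat(sprintf("<mk801_fit> tau = %.4g stimuli, rms residual %.3g%s\n",
              x$tau, x$fit_residual, if (x$no_block) " [no block]" else ""))
  invisible(x)
}

#' Input-output curve summary
#'
#' Summarizes evoked peak amplitudes across stimulation intensities: per
#' intensity, the mean, standard error of the mean and number of
#' responses. SEM is reported as `NA` (not 0) when n = 1.
#'
#' @param responses named list mapping stimulus intensity (names coercible
#'   to numeric, e.g. volts) to a numeric vector of peak amplitudes (pA).
#' @return data.frame with columns `intensity`, `mean`, `sem`, `n`,
#'   ordered by intensity.
#' @export
input_output_curve <- function(responses) {
  if (length(responses) == 0) {
    rrp_abort("no responses supplied", "rrpool_estimation_error")
  }
  intensity <- as.numeric(names(responses))
  if (any(is.na(intensity))) {
    rrp_abort("response list names must be numeric intensities",
              "rrpool_parameter_error")
  }
  out <- data.frame(
    intensity = intensity,
    mean = vapply(responses, mean, numeric(1)),
    sem = vapply(responses, sem, numeric(1)),
    n = vapply(responses, length, integer(1)))
  out <- out[order(out$intensity), , drop = FALSE]
  rownames(out) <- NULL
  out
}
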