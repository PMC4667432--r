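# Synthetic electrophysiology with known ground truth.
#
# Every simulator is deterministic given its seed and returns the exact
# quantities an estimator should recover, so parameter-recovery tests can
# close the loop simulator -> analysis -> ground truth.

#' Bi-exponential synaptic event kernel
#'
#' Difference-of-exponentials waveform
#' `K(t) = c * (exp(-t / tau_decay) - exp(-t / tau_rise))` for t >= 0, with
#' the scale `c` chosen so the peak equals `amplitude`. Its charge integral
#' has the closed form `c * (tau_decay - tau_rise)` (pC when amplitude is
#' in pA and time in s).
#'
#' @param amplitude peak magnitude in pA, > 0.
#' @param tau_rise rise time constant in seconds; 0 < tau_rise < tau_decay.
#' @param tau_decay decay time constant in seconds.
#' @return An object of class `"event_kernel"` with fields `amplitude`,
#'   `tau_rise`, `tau_decay`, `scale`, `t_peak` and `charge` (pC).
#' @examples
#' k <- make_kernel(10, 0.5e-3, 5e-3)
#' k$charge  # closed-form integral, pC
#' @export
make_kernel <- function(amplitude, tau_rise, tau_decay) {
  if (!is.finite(amplitude) || amplitude <= 0) {
    rrp_abort("amplitude must be > 0 (pA)", "rrpool_parameter_error")
  }
  if (!is.finite(tau_rise) || !is.finite(tau_decay) ||
      tau_rise <= 0 || tau_rise >= tau_decay) {
    rrp_abort("need 0 < tau_rise < tau_decay", "rrpool_parameter_error")
  }
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  peak_unscaled <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  sc <- amplitude / peak_unscaled
  structure(list(amplitude = amplitude, tau_rise = tau_rise,
                 tau_decay = tau_decay, scale = sc, t_peak = t_peak,
                 charge = sc * (tau_decay - tau_rise)),
            class = "event_kernel")
}

#' Evaluate an event kernel
#'
#' @param kernel an [make_kernel()] object.
#' @param t times in seconds (vector); the kernel is 0 for t < 0.
#' @return waveform values in pA (positive; callers apply the sign).
#' @export
kernel_eval <- function(kernel, t) {
  stopifnot(inherits(kernel, "event_kernel"))
  out <- numeric(length(t))
  ok <- t >= 0
  out[ok] <- kernel$scale *
    (exp(-t[ok] / kernel$tau_decay) - exp(-t[ok] / kernel$tau_rise))
  out
}

#' @export
print.event_kernel <- function(x, ...) {
  cat(sprintf(
    "<event_kernel> peak %.4g pA, tau_rise %g ms, tau_decay %g ms, charge %.4g pC\n",
    x$amplitude, x$tau_rise * 1000, x$tau_decay * 1000, x$charge))
  invisible(x)
}

# Add `sign * scale * kernel` starting at each onset into `samples`
# (modified copy returned). Tail rendered to 12 decay constants or the end
# of the trace, whichever comes first.
render_events <- function(samples, sampling_rate, t0, kernel, onsets, scales,
                          sign = -1) {
  n <- length(samples)
  tail_len <- min(n, ceiling(12 * kernel$tau_decay * sampling_rate))
  rel_t <- (seq_len(tail_len) - 1) / sampling_rate
  base_wave <- kernel_eval(kernel, rel_t)
  for (j in seq_along(onsets)) {
    i0 <- round((onsets[j] - t0) * sampling_rate) + 1
    if (i0 > n) next
    # fractional-sample alignment: evaluate the kernel at the exact offsets
    frac <- (i0 - 1) / sampling_rate - (onsets[j] - t0)
    idx <- i0:min(n, i0 + tail_len - 1)
    w <- if (abs(frac) < 1e-12) {
      base_wave[seq_along(idx)]
    } else {
      kernel_eval(kernel, rel_t[seq_along(idx)] + frac)
    }
    samples[idx] <- samples[idx] + sign * scales[j] * w
  }
  samples
}

#' Simulate a miniature EPSC recording
#'
#' Homogeneous Poisson event onsets, each rendered as the (negative-going)
#' kernel, summed linearly, plus additive Gaussian noise. Emulates an
#' mEPSC recording in TTX.
#'
#' @param kernel event waveform from [make_kernel()].
#' @param rate event rate in Hz, >= 0.
#' @param duration recording duration in seconds, > 0.
#' @param noise_sd Gaussian noise SD in pA, >= 0.
#' @param sampling_rate sampling rate in Hz (default 10 kHz, the standard
#'   digitization rate for these recordings).
#' @param seed integer RNG seed; the same seed reproduces the trace bitwise.
#' @return list with components `trace` (a [trace()]) and `ground_truth`
#'   (list: `event_onsets` s, `event_charge` pC per event, `seed`).
#' @export
simulate_mepsc_train <- function(kernel, rate, duration, noise_sd = 1,
                                 sampling_rate = 10000, seed = 1) {
  stopifnot(inherits(kernel, "event_kernel"))
  if (!is.finite(rate) || rate < 0) {
    rrp_abort("rate must be >= 0 (Hz)", "rrpool_parameter_error")
  }
  if (!is.finite(duration) || duration <= 0) {
    rrp_abort("duration must be > 0 (s)", "rrpool_parameter_error")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    rrp_abort("noise_sd must be >= 0 (pA)", "rrpool_parameter_error")
  }
  n <- max(2, round(duration * sampling_rate))
  with_seed(seed, {
    n_ev <- stats::rpois(1, rate * duration)
    onset_max <- max(duration - 12 * kernel$tau_decay, duration / 2)
    onsets <- sort(stats::runif(n_ev, 0, onset_max))
    samples <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    samples <- render_events(samples, sampling_rate, 0, kernel, onsets,
                             rep(1, n_ev), sign = -1)
    list(trace = trace(samples, sampling_rate, t0 = 0,
                       channel_label = "mEPSC_sim"),
         ground_truth = list(event_onsets = onsets,
                             event_charge = rep(kernel$charge, n_ev),
                             seed = seed))
  })
}

#' First-order depletion-refill pool recurrence
#'
#' The generative model behind train-based RRP estimation. With pool
#' capacity `RRP`, fusion efficiency `fe` and refill rate constant `alpha`,
#' the available pool `N_i` before stimulus i evolves as
#' \deqn{r(i) = fe N_i, \quad N_i^+ = (1 - fe) N_i,}
#' \deqn{N_{i+1} = RRP - (RRP - N_i^+) e^{-\alpha \Delta t},}
#' with `N_1 = RRP`, so `r(1) = fe * RRP`. When facilitation fields are
#' present in `params`, the fixed fraction `fe` is replaced by a
#' facilitating release fraction `u_i` with `u_1 = fe`: after each
#' stimulus `u <- u + U_f (1 - u)`; between stimuli u relaxes toward `fe`
#' with time constant `facil_tau`. A large `U_f` therefore produces
#' paired-pulse facilitation (PPR > 1) while `U_f = 0` recovers the pure
#' depletion model.
#'
#' @param params a [pool_params()].
#' @param dt interstimulus interval in seconds (scalar), or a vector of the
#'   n - 1 successive intervals for irregular trains.
#' @param n number of stimuli, >= 1.
#' @return numeric vector `r(1..n)` of per-stimulus charges in pC.
#' @examples
#' p <- pool_params(rrp_charge = 10, fe = 0.4, alpha = log(2) / 0.05)
#' r <- pool_recurrence(p, dt = 0.05, n = 5)
#' r[2] / r[1]  # 1 - fe * exp(-alpha * dt) = 0.8
#' @export
pool_recurrence <- function(params, dt, n) {
  stopifnot(inherits(params, "pool_params"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    rrp_abort("n must be a positive count", "rrpool_parameter_error")
  }
  n <- as.integer(n)
  if (length(dt) == 1) dt <- rep(dt, max(0, n - 1))
  if (n > 1 && (length(dt) != n - 1 || any(!is.finite(dt)) || any(dt <= 0))) {
    rrp_abort("dt must be positive (scalar or length n - 1)",
              "rrpool_parameter_error")
  }
  RRP <- params$rrp_charge
  fe <- params$fe
  facil <- !is.null(params$facil_increment) && params$facil_increment > 0
  Uf <- if (facil) params$facil_increment else 0
  r <- numeric(n)
  N <- RRP
  u <- fe   # first release uses the baseline fraction; facilitation
            # accumulates from the first stimulus onward
  for (i in seq_len(n)) {
    r[i] <- u * N
    Npost <- (1 - u) * N
    if (i < n) {
      x <- exp(-params$alpha * dt[i])
      N <- RRP - (RRP - Npost) * x
      if (facil) {
        u <- u + Uf * (1 - u)
        u <- fe + (u - fe) * exp(-dt[i] / params$facil_tau)
      }
    }
  }
  r
}

#' Simulate an evoked EPSC train
#'
#' Per-stimulus charges come from [pool_recurrence()]; each response is the
#' kernel scaled so that its integral equals r(i), rendered negative-going
#' at `stimulus time + latency` (the synaptic delay places the response
#' after the stimulus artefact). Optionally adds a brief rectangular
#' stimulus artefact at each stimulus time, multiplicative per-stimulus
#' charge noise, and additive Gaussian trace noise.
#'
#' @param params a [pool_params()] ground truth.
#' @param train a [stimulus_train()].
#' @param kernel response waveform from [make_kernel()].
#' @param noise_sd additive Gaussian noise SD in pA.
#' @param sampling_rate sampling rate in Hz.
#' @param seed integer RNG seed.
#' @param artefact_amplitude rectangular stimulus-artefact amplitude in pA
#'   (1 ms duration); 0 disables it.
#' @param charge_cv coefficient of variation of multiplicative per-stimulus
#'   charge noise (realized charge = model charge * N(1, charge_cv)); 0
#'   disables it.
#' @param latency synaptic delay from stimulus time to response onset, in
#'   seconds. Must be at least as long as any downstream blanking window
#'   for charges to be fully recoverable.
#' @param tail recording time appended after the last stimulus, s.
#' @return list with components `trace` and `ground_truth` (list:
#'   `stimulus_times`, `r_model` pC (noise-free model charges), `r_realized`
#'   pC (charges actually rendered), `params`, `latency`, `seed`).
#' @export
simulate_evoked_train <- function(params, train, kernel, noise_sd = 0,
                                  sampling_rate = 10000, seed = 1,
                                  artefact_amplitude = 0, charge_cv = 0,
                                  latency = 0.002, tail = 0.25) {
  stopifnot(inherits(params, "pool_params"), inherits(train, "stimulus_train"),
            inherits(kernel, "event_kernel"))
  if (!is.finite(charge_cv) || charge_cv < 0) {
    rrp_abort("charge_cv must be >= 0", "rrpool_parameter_error")
  }
  times <- train$times
  n_stim <- length(times)
  isi <- if (n_stim > 1) diff(times) else tail
  if (kernel$tau_decay >= min(isi) / 2) {
    rrp_warn("kernel decay >= half the interstimulus interval; responses overlap (spill-over correction applies downstream)",
             "rrpool_overlap_warning")
  }
  r_model <- pool_recurrence(params, dt = isi, n = n_stim)
  dur <- times[n_stim] + tail
  n <- max(2, round(dur * sampling_rate))
  with_seed(seed, {
    r_real <- if (charge_cv > 0) {
      pmax(r_model * stats::rnorm(n_stim, 1, charge_cv), 0)
    } else {
      r_model
    }
    samples <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    samples <- render_events(samples, sampling_rate, 0, kernel,
                             times + latency, r_real / kernel$charge,
                             sign = -1)
    if (artefact_amplitude != 0) {
      w <- max(1, round(0.001 * sampling_rate))
      for (tt in times) {
        i0 <- round(tt * sampling_rate) + 1
        idx <- i0:min(n, i0 + w - 1)
        samples[idx] <- samples[idx] + artefact_amplitude
      }
    }
    list(trace = trace(samples, sampling_rate, t0 = 0,
                       channel_label = "EPSC_train_sim"),
         ground_truth = list(stimulus_times = times, r_model = r_model,
                             r_realized = r_real, params = params,
                             latency = latency, seed = seed))
  })
}

#' Simulate progressive MK-801 block of NMDA-EPSC amplitudes
#'
#' MK-801 irreversibly blocks NMDA receptors that open; release sites that
#' release on a stimulus lose their receptor contribution with probability
#' `block_prob`. In mean-field mode the normalized amplitude declines
#' geometrically, `A_n = (1 - pr * block_prob)^(n - 1)`. In binomial mode
#' each of `n_synapses` sites releases and is blocked stochastically.
#'
#' @param pr release probability per site, in \[0, 1].
#' @param block_prob probability an open receptor is blocked on a release,
#'   in \[0, 1].
#' @param n_stim number of stimuli, >= 2 (the experimental protocol uses 80
#'   at 0.1 Hz).
#' @param n_synapses number of release sites (binomial mode only).
#' @param seed integer RNG seed (binomial mode only).
#' @param mode `"meanfield"` (deterministic) or `"binomial"`.
#' @return numeric vector of amplitudes normalized to the first stimulus.
#' @export
simulate_mk801_series <- function(pr, block_prob, n_stim = 80,
                                  n_synapses = NULL, seed = 1,
                                  mode = c("meanfield", "binomial")) {
  mode <- match.arg(mode)
  if (!is.finite(pr) || pr < 0 || pr > 1) {
    rrp_abort("pr must lie in [0, 1]", "rrpool_parameter_error")
  }
  if (!is.finite(block_prob) || block_prob < 0 || block_prob > 1) {
    rrp_abort("block_prob must lie in [0, 1]", "rrpool_parameter_error")
  }
  if (!is.numeric(n_stim) || n_stim < 2) {
    rrp_abort("n_stim must be >= 2", "rrpool_parameter_error")
  }
  n_stim <- as.integer(n_stim)
  if (mode == "meanfield") {
    return((1 - pr * block_prob)^(seq_len(n_stim) - 1))
  }
  if (is.null(n_synapses) || !is.finite(n_synapses) || n_synapses < 1) {
    rrp_abort("binomial mode needs n_synapses >= 1", "rrpool_parameter_error")
  }
  n_synapses <- as.integer(n_synapses)
  with_seed(seed, {
    unblocked <- n_synapses
    amp <- numeric(n_stim)
    for (i in seq_len(n_stim)) {
      released <- stats::rbinom(1, unblocked, pr)
      amp[i] <- released
      unblocked <- unblocked - stats::rbinom(1, released, block_prob)
    }
    if (amp[1] <= 0) {
      rrp_abort("first response released no quanta; cannot normalize",
                "rrpool_estimation_error")
    }
    amp / amp[1]
  })
}

#' Simulate a hypertonic-sucrose response
#'
#' During the application window the (negative-going) current is a steady
#' component plus an exponentially decaying transient whose total integral
#' over the window equals `rrp_charge`; outside the window the current is
#' zero (plus noise).
#'
#' @param rrp_charge charge of the transient component in pC, >= 0.
#' @param release_tau decay time constant of the transient in seconds.
#' @param steady_current steady-state exocytosis current magnitude in pA.
#' @param application_window `c(start, end)` of the application in seconds
#'   (the standard protocol applies sucrose for 10 s).
#' @param noise_sd Gaussian noise SD in pA.
#' @param sampling_rate sampling rate in Hz.
#' @param seed integer RNG seed.
#' @param pad recording time before and after the window, s.
#' @return list with components `trace` and `ground_truth` (list:
#'   `rrp_charge`, `release_tau`, `steady_current`, `window`, `seed`).
#' @export
simulate_sucrose_response <- function(rrp_charge, release_tau, steady_current,
                                      application_window, noise_sd = 0,
                                      sampling_rate = 2000, seed = 1,
                                      pad = 1) {
  if (!is.finite(rrp_charge) || rrp_charge < 0) {
    rrp_abort("rrp_charge must be >= 0 (pC)", "rrpool_parameter_error")
  }
  w <- as.numeric(application_window)
  if (length(w) != 2 || w[2] <= w[1]) {
    rrp_abort("application_window must be c(start, end) with end > start",
              "rrpool_parameter_error")
  }
  L <- w[2] - w[1]
  if (!is.finite(release_tau) || release_tau <= 0 || L < release_tau) {
    rrp_abort("window length must be >= release_tau (> 0)",
              "rrpool_parameter_error")
  }
  dur <- w[2] + pad
  n <- max(2, round(dur * sampling_rate))
  t <- (seq_len(n) - 1) / sampling_rate
  inside <- t >= w[1] & t < w[2]
  current <- numeric(n)
  transient <- exp(-(t[inside] - w[1]) / release_tau)
  # normalize on the sample grid so the windowed sample sum carries
  # exactly rrp_charge (the discrete integral downstream analyses compute)
  if (rrp_charge > 0 && sum(transient) > 0) {
    transient <- transient * rrp_charge / (sum(transient) / sampling_rate)
  } else {
    transient <- transient * 0
  }
  current[inside] <- -(steady_current + transient)
  with_seed(seed, {
    if (noise_sd > 0) current <- current + stats::rnorm(n, 0, noise_sd)
    list(trace = trace(current, sampling_rate, t0 = 0,
                       channel_label = "sucrose_sim"),
         ground_truth = list(rrp_charge = rrp_charge,
                             release_tau = release_tau,
                             steady_current = steady_current,
                             window = w, seed = seed))
  })
}
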