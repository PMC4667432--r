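# Shared fixtures, all built in code at test time.

# Standard mEPSC-like kernel: 0.5 ms rise, 5 ms decay.
std_kernel <- function(amplitude = 50) make_kernel(amplitude, 5e-4, 5e-3)

# Kernel scaled so each event carries `charge_fC` femtocoulombs.
kernel_with_charge <- function(charge_fC, tau_rise = 5e-4, tau_decay = 5e-3) {
  unit <- make_kernel(1, tau_rise, tau_decay)
  make_kernel(fc_to_pc(charge_fC) / unit$charge, tau_rise, tau_decay)
}

# Noise-free EPSC series straight from the pool recurrence (peaks scaled
# proportionally to charge, as for a fixed response waveform).
recurrence_series <- function(params, dt = 0.05, n = 60) {
  r <- pool_recurrence(params, dt, n)
  epsc_series(r = r, peaks = r * 150, dt = dt)
}

# Greedy onset matching within a tolerance window; returns recall/precision.
match_events <- function(detected, truth, tol = 0.002) {
  if (length(truth) == 0 || length(detected) == 0) {
    return(list(recall = NA_real_, precision = NA_real_))
  }
  d <- abs(outer(detected, truth, "-"))
  list(recall = mean(apply(d, 2, min) < tol),
       precision = mean(apply(d, 1, min) < tol))
}
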