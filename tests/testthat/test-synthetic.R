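# Synthetic generators: kernel algebra, the pool recurrence, and the
# trace-level simulators, each validated against an independent oracle
# (quadrature, direct iteration, closed forms, or distributional bounds).

test_that("kernel charge matches adaptive quadrature and scales linearly", {
  k <- make_kernel(10, 0.5e-3, 5e-3)
  # independent oracle: adaptive quadrature of the evaluated waveform
  q <- integrate(function(t) kernel_eval(k, t), 0, Inf,
                 rel.tol = 1e-10)$value
  expect_equal(k$charge, q, tolerance = 1e-6)
  expect_equal(max(kernel_eval(k, seq(0, 0.05, by = 1e-6))), 10,
               tolerance = 1e-6)
  k2 <- make_kernel(20, 0.5e-3, 5e-3)
  expect_equal(k2$charge, 2 * k$charge, tolerance = 1e-12)
  expect_error(make_kernel(10, 5e-3, 5e-3), class = "rrpool_parameter_error")
  expect_error(make_kernel(10, 6e-3, 5e-3), class = "rrpool_parameter_error")
  expect_error(make_kernel(-1, 5e-4, 5e-3), class = "rrpool_parameter_error")
})

test_that("pool recurrence reproduces closed forms and limits", {
  # r(2)/r(1) = 1 - fe * exp(-alpha dt): fe = 0.4, x = 0.5
  p <- pool_params(7.7, 0.4, log(2) / 0.05)
  r <- pool_recurrence(p, 0.05, 4)
  expect_equal(r[2] / r[1], 0.8, tolerance = 1e-12)
  expect_equal(r[1], 0.4 * 7.7, tolerance = 1e-12)

  # alpha -> infinity: full refill, flat train
  r_inf_alpha <- pool_recurrence(pool_params(10, 0.3, 1e9), 0.05, 10)
  expect_equal(r_inf_alpha, rep(3, 10), tolerance = 1e-9)

  # alpha = 0, fe = 1: everything released on the first stimulus
  r_once <- pool_recurrence(pool_params(10, 1, 0), 0.05, 5)
  expect_equal(r_once, c(10, 0, 0, 0, 0), tolerance = 1e-12)

  expect_error(pool_params(10, 0, 2), class = "rrpool_parameter_error")
  expect_error(pool_params(10, 1.2, 2), class = "rrpool_parameter_error")
})

test_that("pool recurrence matches a step-by-step iteration oracle", {
  set.seed(42)
  for (rep in 1:20) {
    fe <- runif(1, 0.05, 0.9)
    alpha <- runif(1, 0, 8)
    RRP <- runif(1, 2, 40)
    dt <- runif(1, 0.02, 0.2)
    n <- 30
    # oracle: literal re-iteration of the model definition
    x <- exp(-alpha * dt)
    N <- RRP
    r_oracle <- numeric(n)
    for (i in 1:n) {
      r_oracle[i] <- fe * N
      N_post <- N - r_oracle[i]
      N <- RRP - (RRP - N_post) * x
    }
    r <- pool_recurrence(pool_params(RRP, fe, alpha), dt, n)
    expect_equal(r, r_oracle, tolerance = 1e-12)
  }
})

test_that("recurrence steady state equals the closed-form ratio at n = 500", {
  set.seed(7)
  for (rep in 1:10) {
    fe <- runif(1, 0.1, 0.9)
    alpha <- runif(1, 0.3, 6)
    dt <- 0.05
    r <- pool_recurrence(pool_params(12, fe, alpha), dt, 500)
    expect_equal(r[500] / r[1], steady_state_ratio(fe, alpha, dt),
                 tolerance = 1e-9)
  }
})

test_that("facilitating recurrence raises early responses and can give PPR > 1", {
  base <- pool_params(10, 0.2, 2)
  fac <- pool_params(10, 0.2, 2, facil_increment = 0.6, facil_tau = 0.3)
  r_b <- pool_recurrence(base, 0.05, 10)
  r_f <- pool_recurrence(fac, 0.05, 10)
  expect_gt(r_f[2] / r_f[1], 1)           # strong facilitation wins
  expect_lt(r_b[2] / r_b[1], 1)           # pure depletion depresses
  # U_f = 0 collapses to the depletion-only model
  fac0 <- pool_params(10, 0.2, 2, facil_increment = 0, facil_tau = 0.3)
  expect_equal(pool_recurrence(fac0, 0.05, 10), r_b, tolerance = 1e-12)
})

test_that("mEPSC simulation is seed-deterministic with Poisson event counts", {
  k <- std_kernel(15)
  a <- simulate_mepsc_train(k, rate = 1, duration = 100, noise_sd = 1.5,
                            seed = 11)
  b <- simulate_mepsc_train(k, rate = 1, duration = 100, noise_sd = 1.5,
                            seed = 11)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$ground_truth$event_onsets, b$ground_truth$event_onsets)
  # Poisson(100): count within 3 sd of the mean for a fixed seed
  expect_lt(abs(length(a$ground_truth$event_onsets) - 100), 3 * sqrt(100))

  zero <- simulate_mepsc_train(k, rate = 0, duration = 5, noise_sd = 1,
                               seed = 1)
  expect_length(zero$ground_truth$event_onsets, 0)
  expect_lt(max(abs(zero$trace$samples)), 6)   # pure noise
  expect_error(simulate_mepsc_train(k, 1, 10, noise_sd = -1),
               class = "rrpool_parameter_error")
})

test_that("evoked-train simulation renders exactly the ground-truth charges", {
  k <- std_kernel(50)
  train <- regular_train(20, 20)
  p <- pool_params(16.3, 0.3, 2)
  sim <- simulate_evoked_train(p, train, k, noise_sd = 0, seed = 3)
  tr <- sim$trace
  gt <- sim$ground_truth
  # oracle: rectangle-rule integration of each response window on the raw
  # trace (no baseline machinery)
  fs <- tr$sampling_rate
  for (i in seq_along(train$times)) {
    t_on <- train$times[i] + gt$latency
    t_off <- if (i < 20) train$times[i + 1] + gt$latency else t_on + 0.2
    idx <- (round(t_on * fs) + 1):(round(t_off * fs))
    q <- -sum(tr$samples[idx]) / fs
    expect_equal(q, gt$r_model[i], tolerance = 1e-3)
  }
  # single stimulus: base case r(1) = fe * RRP
  sim1 <- simulate_evoked_train(p, stimulus_train(0.05), k, seed = 1)
  q1 <- -sum(sim1$trace$samples) / sim1$trace$sampling_rate
  expect_equal(q1, 0.3 * 16.3, tolerance = 1e-3)
})

test_that("different seeds change only the noise, not the model charges", {
  k <- std_kernel(50)
  train <- regular_train(15, 20)
  p <- pool_params(10, 0.25, 2)
  s1 <- simulate_evoked_train(p, train, k, noise_sd = 2, seed = 1)
  s2 <- simulate_evoked_train(p, train, k, noise_sd = 2, seed = 2)
  expect_false(identical(s1$trace$samples, s2$trace$samples))
  expect_identical(s1$ground_truth$r_model, s2$ground_truth$r_model)
  # with charge noise, realized charges differ but stay centred on the model
  s3 <- simulate_evoked_train(p, train, k, seed = 5, charge_cv = 0.1)
  expect_false(identical(s3$ground_truth$r_realized,
                         s3$ground_truth$r_model))
})

test_that("MK-801 series: geometric mean-field decay and binomial agreement", {
  # pr * block = 0.5: exact halving
  a <- simulate_mk801_series(1, 0.5, 5)
  expect_equal(a, c(1, 0.5, 0.25, 0.125, 0.0625), tolerance = 1e-12)
  # no release, no block
  expect_equal(simulate_mk801_series(0, 0.9, 10), rep(1, 10))
  # law of large numbers: binomial mode tracks mean-field
  pr <- 0.4; b <- 0.5; ns <- 10000
  bin <- simulate_mk801_series(pr, b, n_stim = 40, n_synapses = ns,
                               seed = 9, mode = "binomial")
  mf <- simulate_mk801_series(pr, b, n_stim = 40)
  # binomial SE of the normalized amplitude at stimulus n is of order
  # sqrt(mf (1 - mf * pr * ...)) / sqrt(ns * pr); use a conservative bound
  se <- sqrt(mf / (ns * pr)) + 1 / sqrt(ns * pr)
  expect_true(all(abs(bin - mf) <= 3 * se + 3 / (ns * pr)))
  expect_error(simulate_mk801_series(0.5, 0.5, 10, n_synapses = 0,
                                     mode = "binomial"),
               class = "rrpool_parameter_error")
})

test_that("sucrose simulator: windowed integral equals the RRP charge", {
  s <- simulate_sucrose_response(rrp_charge = 20, release_tau = 1,
                                 steady_current = 0, application_window =
                                   c(0, 10), noise_sd = 0)
  fs <- s$trace$sampling_rate
  q <- -sum(s$trace$samples) / fs
  expect_equal(q, 20, tolerance = 1e-4)
  # >= 99% of the transient charge falls in the first 5 tau
  t <- trace_times(s$trace)
  early <- -sum(s$trace$samples[t < 5]) / fs
  expect_gt(early / q, 0.99)
  # degenerate: no transient leaves only the steady rectangle
  s0 <- simulate_sucrose_response(0, 1, 10, c(1, 11), noise_sd = 0)
  inside <- trace_times(s0$trace) >= 1 & trace_times(s0$trace) < 11
  expect_equal(unique(s0$trace$samples[inside]), -10)
  expect_error(simulate_sucrose_response(-1, 1, 0, c(0, 10)),
               class = "rrpool_parameter_error")
  expect_error(simulate_sucrose_response(5, 3, 0, c(0, 2)),
               class = "rrpool_parameter_error")
})
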