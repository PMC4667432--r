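# RRP estimation: two-equation train estimator, sucrose transients,
# facilitation-depression fits, and their parameter-recovery closure.

test_that("steady-state ratio evaluates its closed form", {
  expect_equal(steady_state_ratio(0.5, log(2) / 0.05, 0.05), 2 / 3,
               tolerance = 1e-12)
  expect_equal(steady_state_ratio(1, log(2) / 0.05, 0.05), 0.5,
               tolerance = 1e-12)
  expect_equal(steady_state_ratio(0.3, 1e9, 0.05), 1, tolerance = 1e-9)
  expect_error(steady_state_ratio(0, 2, 0.05),
               class = "rrpool_parameter_error")
})

test_that("cumulative charge is a running sum", {
  s <- epsc_series(r = c(2, 1, 1), peaks = c(2, 1, 1), dt = 0.05)
  expect_equal(cumulative_charge(s), c(2, 3, 4))
  expect_equal(cumulative_charge(rep(0, 5)), rep(0, 5))
})

test_that("train estimator recovers noiseless model parameters within 1%", {
  s <- recurrence_series(pool_params(16.3, 0.3, 2), dt = 0.05, n = 60)
  for (method in c("fit", "two_equation")) {
    fit <- estimate_rrp_train(s, method = method)
    expect_true(fit$converged)
    expect_equal(fit$fe, 0.3, tolerance = 0.01)
    expect_equal(fit$alpha, 2, tolerance = 0.01)
    expect_equal(fit$rrp_charge, 16.3, tolerance = 0.01)
  }
})

test_that("estimator-simulator closure holds over random parameter draws", {
  set.seed(20)
  n_draws <- 50
  for (i in seq_len(n_draws)) {
    fe <- runif(1, 0.1, 0.6)
    alpha <- runif(1, 0.5, 5)
    RRP <- runif(1, 5, 30)
    s <- recurrence_series(pool_params(RRP, fe, alpha), dt = 0.05, n = 60)
    method <- if (i %% 2 == 0) "fit" else "two_equation"
    fit <- estimate_rrp_train(s, method = method)
    errs <- abs(c(fit$fe / fe, fit$alpha / alpha,
                  fit$rrp_charge / RRP) - 1)
    expect_lt(max(errs), 0.01)
  }
})

test_that("with 10% charge noise the median RRP error stays within 10%", {
  set.seed(77)
  errs <- vapply(1:50, function(i) {
    fe <- runif(1, 0.1, 0.6)
    alpha <- runif(1, 0.5, 5)
    RRP <- runif(1, 5, 30)
    r <- pool_recurrence(pool_params(RRP, fe, alpha), 0.05, 60)
    r_noisy <- pmax(r * rnorm(60, 1, 0.1), 1e-6)
    s <- epsc_series(r_noisy, r_noisy * 150, 0.05)
    fit <- tryCatch(suppressWarnings(estimate_rrp_train(s)),
                    error = function(e) NULL)
    if (is.null(fit) || is.na(fit$rrp_charge)) return(NA_real_)
    abs(fit$rrp_charge / RRP - 1)
  }, numeric(1))
  expect_lte(median(errs, na.rm = TRUE), 0.10)
})

test_that("the solver agrees with an exhaustive grid-search oracle", {
  set.seed(31)
  for (i in 1:10) {
    fe <- runif(1, 0.15, 0.6)
    alpha <- runif(1, 0.5, 5)
    RRP <- runif(1, 5, 30)
    dt <- 0.05
    n <- 60
    s <- recurrence_series(pool_params(RRP, fe, alpha), dt = dt, n = n)
    fit <- estimate_rrp_train(s, method = "two_equation")
    rho <- s$r_inf / s$r[1]
    S_obs <- sum(s$r)
    objective <- function(f, a) {
      e1 <- steady_state_ratio(f, a, dt) - rho
      rr <- pool_recurrence(pool_params(s$r[1] / f, f, a), dt, n)
      e2 <- (sum(rr) - S_obs) / S_obs
      e1^2 + e2^2
    }
    # oracle 1: exhaustive 200 x 200 grid on the same two squared
    # residuals; the solver must do at least as well as every grid point
    fe_grid <- seq(0.005, 1, length.out = 200)
    al_grid <- seq(0.01, 10, length.out = 200)
    resid <- outer(fe_grid, al_grid, Vectorize(objective))
    expect_lte(objective(fit$fe, fit$alpha), min(resid))
    # oracle 2: exhaustive fe grid along the steady-state (E1) manifold --
    # the well-conditioned axis of the valley -- must place the optimum
    # within one grid cell of the solver's fe
    rho_alpha <- function(f) -log((1 - rho) / (1 - rho * (1 - f))) / dt
    resid_1d <- vapply(fe_grid, function(f) objective(f, rho_alpha(f)),
                       numeric(1))
    best_fe <- fe_grid[which.min(resid_1d)]
    expect_lt(abs(fit$fe - best_fe), diff(fe_grid[1:2]) + 1e-9)
  }
})

test_that("pure-depletion trains are recovered with alpha near zero", {
  r <- pool_recurrence(pool_params(12, 0.35, 0), 0.05, 60)
  r <- pmax(r, 1e-9)
  s <- epsc_series(r, r * 150, 0.05)
  fit <- estimate_rrp_train(s)
  expect_lt(fit$alpha, 0.05)
  expect_equal(fit$rrp_charge, 12, tolerance = 0.02)
  # cumulative-depletion identity: RRP = sum r / (1 - (1 - fe)^n)
  expect_equal(fit$rrp_charge,
               sum(r) / (1 - (1 - fit$fe)^60), tolerance = 0.02)
})

test_that("RRP = r(1)/fe is decreasing in the solved fe", {
  s <- recurrence_series(pool_params(16.3, 0.3, 2), dt = 0.05, n = 60)
  fes <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(s$r[1] / fes) < 0))
})

test_that("a non-depressing series is flagged as unidentifiable", {
  r <- rep(5, 60)
  s <- epsc_series(r, r * 150, dt = 0.05)
  expect_warning(fit <- estimate_rrp_train(s),
                 class = "rrpool_facilitation_warning")
  expect_false(fit$converged)
  expect_true(is.na(fit$fe))
  short <- epsc_series(c(5, 4), c(500, 400), 0.05)
  expect_error(estimate_rrp_train(short), class = "rrpool_parameter_error")
})

test_that("WT-scale and KO-scale cohorts keep their ordering", {
  # cohorts whose true pool sizes differ two-fold stay ordered in >= 95%
  # of replicate cohort pairs
  set.seed(12)
  n_rep <- 100
  ordered_ok <- logical(n_rep)
  for (rep in seq_len(n_rep)) {
    mean_est <- vapply(c(16.3, 8.7), function(RRP) {
      ests <- vapply(1:5, function(j) {
        r <- pool_recurrence(pool_params(RRP, 0.3, 2), 0.05, 60)
        r_noisy <- pmax(r * rnorm(60, 1, 0.1), 1e-6)
        s <- epsc_series(r_noisy, r_noisy * 150, 0.05)
        suppressWarnings(estimate_rrp_train(s))$rrp_charge
      }, numeric(1))
      mean(ests, na.rm = TRUE)
    }, numeric(1))
    ordered_ok[rep] <- mean_est[1] > mean_est[2]
  }
  expect_gte(mean(ordered_ok), 0.95)
})

test_that("sucrose estimator subtracts steady-state exocytosis", {
  # rectangle 100 pA above a 10 pA steady level for 2 s inside a 10 s window
  fs <- 1000
  t <- (seq_len(12 * fs) - 1) / fs
  x <- numeric(length(t))
  x[t >= 1 & t < 11] <- -10
  x[t >= 1 & t < 3] <- -110
  est <- estimate_rrp_sucrose(trace(x, fs), c(1, 11))
  expect_equal(est$transient_charge, 200, tolerance = 0.01)
  expect_equal(est$steady_state_current, 10, tolerance = 1e-6)
  # simulator self-consistency
  sim <- simulate_sucrose_response(20, 1, 10, c(1, 11), noise_sd = 0)
  est2 <- estimate_rrp_sucrose(sim$trace, c(1, 11))
  expect_equal(est2$transient_charge, 20, tolerance = 0.02)
  # flat trace: zero transient
  flat <- estimate_rrp_sucrose(trace(rep(-5, 5000), 1000), c(0, 4))
  expect_equal(flat$transient_charge, 0, tolerance = 1e-9)
  expect_error(estimate_rrp_sucrose(trace(rep(0, 4000), 1000), c(0, 0.5)),
               class = "rrpool_parameter_error")
})

test_that("facilitation-depression fit recovers its own parameters", {
  truth <- pool_params(100 * 0.118, 0.2, 2, facil_increment = 0.2,
                       facil_tau = 0.1)
  s <- recurrence_series(truth, dt = 0.05, n = 60)
  fit <- fit_facilitation_model(s, quantal_size = 0.118)
  expect_true(fit$converged)
  expect_equal(fit$rrp_quanta, 100, tolerance = 0.05)
  expect_equal(fit$fe, 0.2, tolerance = 0.05)
  expect_equal(fit$alpha, 2, tolerance = 0.05)
  expect_equal(fit$facil_increment, 0.2, tolerance = 0.05)
  expect_equal(fit$facil_tau, 0.1, tolerance = 0.05)
})

test_that("nested in the depletion-only model, both estimators agree", {
  s <- recurrence_series(pool_params(16.3, 0.3, 2), dt = 0.05, n = 60)
  facil <- fit_facilitation_model(s, quantal_size = 0.118)
  train <- estimate_rrp_train(s)
  expect_equal(facil$rrp_charge, train$rrp_charge, tolerance = 0.05)
  expect_lt(facil$facil_increment, 0.05)
})

test_that("garbage input is flagged instead of silently fitted", {
  set.seed(2)
  r <- abs(rnorm(30, 1, 0.8)) + 0.05
  s <- epsc_series(r, r * 150, 0.05)
  expect_warning(fit <- fit_facilitation_model(s, 0.118),
                 class = "rrpool_fit_warning")
  expect_false(fit$converged)
})
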