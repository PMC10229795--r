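test_that("least squares on exact Weibull points recovers parameters to machine precision", {
  set.seed(8)
  for (i in 1:10) {
    g <- runif(1, 0.6, 2.5)
    l <- runif(1, 0.005, 0.2)
    t <- seq(0.5, 30, by = 0.5)
    curve <- tibble::tibble(time = t, survival = exp(-l * t^g))
    fit <- fit_weibull_ls(curve)
    expect_equal(fit$params$gamma, g, tolerance = 1e-9)
    expect_equal(fit$params$lambda, l, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  }
  # exponential points give a unit shape
  t <- 1:20
  fit <- fit_weibull_ls(tibble::tibble(time = t, survival = exp(-0.1 * t)))
  expect_equal(fit$params$gamma, 1, tolerance = 1e-9)
  expect_error(fit_weibull_ls(tibble::tibble(time = 1:2,
                                             survival = c(0.9, 0.5))),
               "at least 3")
})

test_that("least squares stays within tolerance under digitization noise", {
  g_true <- 1.4; l_true <- 0.05
  t <- seq(1, 40, by = 1)
  truth <- tibble::tibble(time = t, survival = exp(-l_true * t^g_true))
  errs <- vapply(1:100, function(s) {
    noisy <- digitize(truth, grid = t, noise_sd = 0.01, seed = s)
    fit_weibull_ls(noisy)$params$gamma - g_true
  }, numeric(1))
  expect_true(all(abs(errs) < 0.1))
})

test_that("maximum likelihood recovers generating parameters and sits at the optimum", {
  ipd <- simulate_ipd(2000, gamma = 1.715, lambda = 0.005, seed = 42)
  fit <- fit_weibull_mle(ipd)
  # the shape's sampling error at n = 2000 is ~1.6%, so a single draw is a
  # sound 5% check; the rate's is ~10%, so its 5% check is on the mean
  # recovery over seeded replicates (a recovery simulation)
  expect_lt(abs(fit$params$gamma - 1.715) / 1.715, 0.05)
  lambda_hat <- vapply(1:50, function(s) {
    fit_weibull_mle(simulate_ipd(2000, gamma = 1.715, lambda = 0.005,
                                 seed = s))$params$lambda
  }, numeric(1))
  expect_lt(abs(mean(lambda_hat) - 0.005) / 0.005, 0.05)
  expect_equal(fit$n_events, 2000)

  # independent check: our own censored log-likelihood cannot be improved
  # from the fitted point
  negll <- function(par) {
    -weibull_loglik(weibull_params(gamma = exp(par[1]), lambda = exp(par[2])),
                    ipd)
  }
  start <- c(log(fit$params$gamma), log(fit$params$lambda))
  opt <- optim(start, negll, method = "BFGS")
  expect_lt(-opt$value - weibull_loglik(fit$params, ipd), 1e-4)
  expect_equal(weibull_loglik(fit$params, ipd), fit$loglik, tolerance = 1e-6)
})

test_that("the exponential special case matches its closed-form estimator", {
  ipd <- simulate_ipd(3000, gamma = 1, lambda = 0.2, seed = 5)
  fit <- fit_weibull_mle(ipd)
  closed_form <- sum(ipd$event) / sum(ipd$time)
  expect_lt(abs(fit$params$gamma - 1), 0.05)
  expect_lt(abs(fit$params$lambda - closed_form) / closed_form, 0.05)
  expect_error(fit_weibull_mle(tibble::tibble(time = c(1, 2),
                                              event = c(0, 0))),
               "at least one event")
})

test_that("least squares and maximum likelihood agree on clean large samples", {
  ipd <- simulate_ipd(2000, gamma = 1.3, lambda = 0.04, seed = 33)
  mle <- fit_weibull_mle(ipd)
  ls <- fit_weibull_ls(km_estimate(ipd))
  expect_lt(abs(mle$params$gamma - ls$params$gamma) / mle$params$gamma, 0.1)
  expect_lt(abs(mle$params$lambda - ls$params$lambda) / mle$params$lambda, 0.1)
})

test_that("fitted AFT forms round-trip through the shape/rate conversion", {
  ipd <- simulate_ipd(500, gamma = 1.5, lambda = 0.03, seed = 12)
  for (fit in list(fit_weibull_mle(ipd),
                   fit_weibull_ls(km_estimate(ipd)))) {
    p <- fit$params
    back <- aft_to_weibull(p$intercept, p$log_scale)
    expect_equal(back$gamma, p$gamma, tolerance = 1e-9)
    expect_equal(back$lambda, p$lambda, tolerance = 1e-9)
  }
})

test_that("IPD reconstruction inverts the product-limit construction", {
  # no censoring: drop positions come back exactly
  ipd <- tibble::tibble(time = c(2, 4, 5, 7, 9, 12), event = 1)
  km <- km_estimate(ipd)
  rec <- reconstruct_ipd(km, initial_n = 6)
  expect_equal(sort(rec$time[rec$event == 1]), ipd$time)
  expect_equal(sum(rec$event == 0), 0)

  # a curve that never drops is all censoring
  flat <- tibble::tibble(time = c(1, 2, 3), survival = c(1, 1, 1))
  rec_flat <- reconstruct_ipd(flat, initial_n = 10)
  expect_true(all(rec_flat$event == 0))
  expect_equal(nrow(rec_flat), 10)

  # non-monotone input is rejected
  expect_error(
    reconstruct_ipd(tibble::tibble(time = c(1, 2), survival = c(0.5, 0.8)),
                    initial_n = 10),
    "non-increasing"
  )
})

test_that("round trip simulate -> KM -> reconstruct -> refit stays within sampling tolerance", {
  ipd <- simulate_ipd(300, gamma = 1.4, lambda = 0.05,
                      censoring = "exponential", cens_rate = 0.015, seed = 21)
  km <- km_estimate(ipd)
  grid <- seq(1, stats::quantile(ipd$time, 0.9), length.out = 25)
  digitized <- digitize(km, grid = grid, noise_sd = 0)
  rec <- reconstruct_ipd(digitized, initial_n = 300)
  km_rec <- km_estimate(rec)
  # the reconstructed KM tracks the input curve
  step_in <- stats::stepfun(km$time, c(1, km$survival))
  step_out <- stats::stepfun(km_rec$time, c(1, km_rec$survival))
  expect_lt(max(abs(step_in(grid) - step_out(grid))), 0.02)
  refit <- fit_weibull_mle(rec)
  expect_lt(abs(refit$params$gamma - 1.4) / 1.4, 0.15)
  expect_lt(abs(refit$params$lambda - 0.05) / 0.05, 0.35)
})

test_that("a risk table converts unexplained attrition into within-interval censoring", {
  curve <- tibble::tibble(time = c(0, 5, 10), survival = c(1, 0.8, 0.7))
  risk <- tibble::tibble(time = c(0, 5, 10), n_at_risk = c(100, 70, 50))
  rec <- reconstruct_ipd(curve, initial_n = 100, risk_table = risk)
  expect_gt(sum(rec$event == 0 & rec$time < 10), 0)
  expect_equal(nrow(rec), 100)
  km_rec <- km_estimate(rec)
  step_out <- stats::stepfun(km_rec$time, c(1, km_rec$survival))
  expect_lt(abs(step_out(5) - 0.8), 0.02)
})
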