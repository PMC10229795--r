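test_that("occupancy is conserved and death monotone for every packaged arm model", {
  s <- model_settings()
  for (models in all_packaged_arm_models()) {
    for (rule in c("progressive", "partitioned")) {
      tr <- run_trace(models$os, models$pfs, s, rule)
      expect_equal(nrow(tr), 175)
      expect_true(all(abs(tr$occ_pfs + tr$occ_pd + tr$occ_dead - 1) < 1e-9))
      expect_true(all(tr$occ_pfs >= 0 & tr$occ_pfs <= 1))
      expect_true(all(tr$occ_pd >= 0 & tr$occ_pd <= 1))
      expect_true(all(diff(tr$occ_dead) >= -1e-12))
      expect_true(all(tr$disc_factor > 0 & tr$disc_factor <= 1))
      expect_true(all(diff(tr$disc_factor) < 0))
      # cycle 0: everyone progression-free
      expect_equal(tr$occ_pfs[1], 1)
      expect_equal(tr$occ_pd[1], 0)
      expect_equal(tr$occ_dead[1], 0)
    }
  }
})

test_that("identical OS and PFS curves leave the progressed state empty under partitioning", {
  p <- weibull_params(gamma = 1.5, lambda = 0.03)
  tr <- run_trace(p, p, rule = "partitioned")
  expect_true(all(tr$occ_pd == 0))
  expect_equal(tr$occ_pfs, 1 - tr$occ_dead)
})

test_that("discount factors follow exact elapsed time at the annual rate", {
  s <- model_settings()
  expect_equal(discount_factor(0, s), 1)
  # one full year elapsed
  s1 <- model_settings(cycle_days = 365.25)
  expect_equal(discount_factor(1, s1), 1 / 1.03)
  expect_equal(discount_factor(174, s),
               1.03^(-(174 * 21 / 365.25)), tolerance = 1e-12)
  expect_error(discount_factor(-1, s), "non-negative")
})

test_that("undiscounted progression-free time matches the restricted-mean oracle", {
  s <- model_settings(discount_annual = 0)
  spec <- builtin_choice01("ITT")
  for (arm in c("toripalimab", "placebo")) {
    pfs <- spec$survival[[arm]]$pfs
    tr <- run_trace(spec$survival[[arm]]$os, pfs, s, "partitioned")
    cyc_months <- s$cycle_days / 30.4375
    lys <- sum((head(tr$occ_pfs, -1) + tail(tr$occ_pfs, -1)) / 2) * cyc_months
    oracle <- weibull_mean(pfs, cap = max(tr$time), step = 0.01)
    expect_equal(lys, oracle, tolerance = 0.01)
  }
})

test_that("accrual reproduces closed forms for simple cohorts", {
  s0 <- model_settings(discount_annual = 0, horizon_years = 1)
  # effectively immortal cohort: one year in PFS at utility 0.673
  p_immortal <- weibull_params(gamma = 1, lambda = 1e-12)
  tr <- run_trace(p_immortal, p_immortal, s0, "partitioned")
  res <- accumulate(tr, cost_item("none", "both", "PFS", 0), utility_set(),
                    s0, "placebo")
  # quantized to whole cycles: ceil(1y / 21d) cycles of 21 days
  expect_equal(res$total_qaly, 0.673 * n_cycles(s0) * 21 / 365.25,
               tolerance = 1e-9)
  expect_equal(res$total_cost, 0)

  # zero utilities and zero costs give an all-zero result
  u0 <- utility_set(u_pfs = 0, u_pd = 0, pfs_low = 0, pfs_high = 0,
                    pd_low = 0, pd_high = 0)
  res0 <- accumulate(tr, cost_item("none", "both", "PFS", 0), u0, s0, "placebo")
  expect_equal(res0$total_qaly, 0)
  expect_equal(res0$total_cost, 0)

  # a single per-cycle PFS cost on an exponential curve equals
  # cost x (restricted mean PFS time / cycle length) up to trapezoid error
  s10 <- model_settings(discount_annual = 0)
  p <- weibull_params(gamma = 1, lambda = 0.08)
  tr2 <- run_trace(p, p, s10, "partitioned")
  res2 <- accumulate(tr2, cost_item("drug", "both", "PFS", 100,
                                    application = "per_cycle"),
                     utility_set(), s10, "placebo")
  cyc_months <- s10$cycle_days / 30.4375
  expected <- 100 * weibull_mean(p, cap = max(tr2$time), step = 0.001) / cyc_months
  expect_equal(res2$total_cost, expected, tolerance = 0.01)

  # a one-off cost at cycle 0 accrues once, undiscounted, at full occupancy
  res3 <- accumulate(tr2, cost_item("ae", "both", "PFS", 138,
                                    application = "one_off"),
                     utility_set(), s10, "placebo")
  expect_equal(res3$total_cost, 138)
})

test_that("per-month, per-cycle and windowed applications scale as documented", {
  s <- model_settings(discount_annual = 0)
  p <- weibull_params(gamma = 1, lambda = 0.05)
  tr <- run_trace(p, p, s, "partitioned")
  per_cycle <- accumulate(tr, cost_item("x", "both", "PFS", 100,
                                        application = "per_cycle"),
                          utility_set(), s, "placebo")$total_cost
  per_month <- accumulate(tr, cost_item("x", "both", "PFS", 100,
                                        application = "per_month"),
                          utility_set(), s, "placebo")$total_cost
  expect_equal(per_month / per_cycle, 21 / 30.4375, tolerance = 1e-9)

  # restricting the window reduces the accrual to the early cycles only
  windowed <- accumulate(tr, cost_item("x", "both", "PFS", 100,
                                       application = "per_cycle",
                                       start_cycle = 0, stop_cycle = 5),
                         utility_set(), s, "placebo")$total_cost
  w <- (head(tr$occ_pfs, -1) + tail(tr$occ_pfs, -1)) / 2
  expect_equal(windowed, 100 * sum(w[1:6]), tolerance = 1e-9)
  expect_lt(windowed, per_cycle)
})

test_that("discounting can only shrink totals and QALYs are bounded by the horizon", {
  s <- model_settings()
  s_nodisc <- model_settings(discount_annual = 0)
  for (pop in c("ITT", "squamous")) {
    spec <- builtin_choice01(pop)
    for (arm in c("toripalimab", "placebo")) {
      disc <- run_arm(spec, arm, s)
      undisc <- run_arm(spec, arm, s_nodisc)
      expect_lt(disc$total_cost, undisc$total_cost)
      expect_lt(disc$total_qaly, undisc$total_qaly)
      expect_lt(undisc$total_qaly,
                s$horizon_years * spec$utilities$u_pfs)
      # state splits add up
      expect_equal(disc$cost_pfs + disc$cost_pd, disc$total_cost,
                   tolerance = 1e-9)
      expect_equal(disc$qaly_pfs + disc$qaly_pd, disc$total_qaly,
                   tolerance = 1e-9)
    }
  }
})

test_that("results are stable under cycle-length refinement", {
  spec <- builtin_choice01("ITT")
  for (rule in c("progressive", "partitioned")) {
    coarse <- run_arm(spec, "toripalimab", model_settings(), rule)
    fine <- run_arm(spec, "toripalimab", model_settings(cycle_days = 10.5), rule)
    expect_lt(abs(fine$total_qaly - coarse$total_qaly) / coarse$total_qaly,
              0.005)
  }
})

test_that("identical inputs give identical arm results", {
  spec <- symmetric_spec()
  a <- run_arm(spec, "toripalimab")
  b <- run_arm(spec, "placebo")
  expect_equal(a$total_cost, b$total_cost)
  expect_equal(a$total_qaly, b$total_qaly)
})
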