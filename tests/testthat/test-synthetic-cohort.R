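test_that("inverse-transform event times match closed forms", {
  s1 <- sim_setting(gamma = 1, lam = 1, beta_w = 0, beta_x = 0, rho = 0,
                    censor_time = 1)
  expect_equal(draw_event_times(s1, lp = 0, u = exp(-2)), 2)
  s2 <- sim_setting(gamma = 2, lam = 1, beta_w = 0, beta_x = 0, rho = 0,
                    censor_time = 1)
  expect_equal(draw_event_times(s2, lp = 0, u = exp(-4)), 2)
  # scaling by the linear predictor: S(t|z) = exp(-lam t^g e^lp)
  expect_equal(draw_event_times(s1, lp = log(2), u = exp(-2)), 1)
})

test_that("marginal survival of simulated latent times matches the Weibull model", {
  s <- sim_setting(gamma = 0.5, lam = 0.3, beta_w = 0, beta_x = 0, rho = 0,
                   censor_time = Inf)
  n <- 1e5
  tt <- with_seed <- NULL
  set.seed(31)
  tt <- draw_event_times(s, lp = rep(log(2), n))
  for (t0 in c(0.5, 1, 2)) {
    expect_lt(abs(mean(tt > t0) - exp(-0.3 * sqrt(t0) * 2)), 0.01)
  }
  # Kolmogorov-Smirnov distance against the closed-form survival
  Fhat <- stats::ecdf(tt)
  grid <- stats::quantile(tt, probs = seq(0.01, 0.99, by = 0.01))
  ks <- max(abs((1 - Fhat(grid)) - exp(-0.3 * grid^0.5 * 2)))
  expect_lt(ks, 0.01)
})

test_that("cohort generator: correlation, censoring, reproducibility", {
  s <- sim_setting(gamma = 1, lam = 0.5, beta_w = log(2), beta_x = log(2),
                   rho = 0, n_cohort = 1e5, n_case_sample = 10,
                   n_control_sample = 10, censor_time = 1)
  co <- simulate_cohort(s, seed = 5)
  expect_lt(abs(cor(co$w, co$x)), 0.01)
  expect_true(all(co$time > 0))
  expect_true(all(co$event %in% c(0, 1)))
  expect_setequal(unique(co$stratum), 1:2)

  s_inf <- sim_setting(gamma = 1, lam = 0.5, beta_w = 0, beta_x = 0, rho = 0,
                       n_cohort = 2000, n_case_sample = 10,
                       n_control_sample = 10, censor_time = Inf)
  expect_true(all(simulate_cohort(s_inf, seed = 1)$event == 1))

  co2 <- simulate_cohort(s, seed = 5)
  expect_identical(co, co2)
  co3 <- simulate_cohort(s, seed = 6)
  expect_false(identical(co$time, co3$time))
})

test_that("correlated scenario induces the requested covariate correlation", {
  s <- sim_setting(gamma = 1, lam = 0.5, beta_w = 0, beta_x = 0, rho = 0.5,
                   n_cohort = 1e5, n_case_sample = 10, n_control_sample = 10,
                   censor_time = 1)
  co <- simulate_cohort(s, seed = 9)
  expect_lt(abs(cor(co$w, co$x) - 0.5), 0.01)
})

test_that("scale calibration solves the closed forms and is self-consistent", {
  # exponential baseline, fixed horizon: 1 - exp(-lam) = target
  expect_equal(calibrate_scale(1, 0, 0, 0, 1, 1 - exp(-1), accrual = 0), 1,
               tolerance = 1e-6)
  expect_equal(calibrate_scale(1, 0, 0, 0, 1, 0.10, accrual = 0), -log(0.90),
               tolerance = 1e-6)
  # re-simulation reproduces the target within Monte-Carlo error
  s <- sim_setting(gamma = 1, beta_w = 0, beta_x = 0, rho = 0,
                   target_case_prop = 0.10, n_cohort = 1e5,
                   n_case_sample = 10, n_control_sample = 10,
                   censor_time = 1, accrual = 0)
  expect_lt(abs(mean(simulate_cohort(s, seed = 3)$event) - 0.10), 0.005)
  # with covariate effects, staggered entry and correlation
  s2 <- sim_setting(gamma = 0.5, beta_w = log(2), beta_x = log(2), rho = 0.5,
                    target_case_prop = 0.22, n_cohort = 1e5,
                    n_case_sample = 10, n_control_sample = 10)
  expect_lt(abs(mean(simulate_cohort(s2, seed = 4)$event) - 0.22), 0.01)
  expect_error(calibrate_scale(1, 0, 0, 0, 1, 1.2), "infeasib")
})

test_that("case proportion is monotone in the scale and the horizon", {
  base <- sim_setting(gamma = 0.7, lam = 1, beta_w = log(2), beta_x = log(2),
                      rho = 0.5, censor_time = 1)
  props <- vapply(c(0.1, 0.3, 1, 3, 10),
                  function(l) expected_case_prop(base, lam = l), 0)
  expect_true(all(diff(props) > 0))
  props_c <- vapply(c(0.25, 0.5, 1, 2, 4), function(cc) {
    s <- sim_setting(gamma = 0.7, lam = 1, beta_w = log(2), beta_x = log(2),
                     rho = 0.5, censor_time = cc)
    expected_case_prop(s)
  }, 0)
  expect_true(all(diff(props_c) > 0))
})

test_that("parameter validation rejects degenerate settings", {
  expect_error(sim_setting(gamma = -1, lam = 1), "gamma")
  expect_error(sim_setting(gamma = 1, lam = -1), "lam")
  expect_error(sim_setting(gamma = 1, lam = 1, rho = 1.5), "rho")
  expect_error(sim_setting(gamma = 1, lam = 1, n_cohort = 100,
                           n_case_sample = 60, n_control_sample = 60),
               "budget")
  expect_error(sim_setting(gamma = 1), "lam or target_case_prop")
  s <- sim_setting(gamma = 1, lam = 1)
  expect_error(draw_event_times(s, lp = Inf), "finite")
})

test_that("binary expensive covariate is supported with latent correlation", {
  s <- sim_setting(gamma = 1, lam = 0.5, beta_w = log(2), beta_x = log(2),
                   rho = 0.5, n_cohort = 5e4, n_case_sample = 10,
                   n_control_sample = 10, censor_time = 1, x_dist = "binary")
  co <- simulate_cohort(s, seed = 8)
  expect_setequal(unique(co$x), c(0, 1))
  expect_lt(abs(mean(co$x) - 0.5), 0.01)
  expect_gt(cor(co$w, co$x), 0.2)
  # calibration also works for the binary support
  s2 <- sim_setting(gamma = 1, beta_w = log(2), beta_x = log(2), rho = 0.5,
                    target_case_prop = 0.15, n_cohort = 5e4,
                    n_case_sample = 10, n_control_sample = 10,
                    censor_time = 1, x_dist = "binary")
  expect_lt(abs(mean(simulate_cohort(s2, seed = 2)$event) - 0.15), 0.01)
})

test_that("make_strata yields balanced, exhaustive labels", {
  set.seed(1)
  w <- rnorm(1000)
  st <- make_strata(w, 2)
  expect_setequal(unique(st), 1:2)
  expect_equal(sum(st == 1), 500)
  stb <- make_strata(rbinom(50, 1, 0.5), 2)
  expect_setequal(unique(stb), 1:2)
  st4 <- make_strata(w, 4)
  expect_setequal(unique(st4), 1:4)
})
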