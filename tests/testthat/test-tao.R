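test_that("complete data reduces the EM to the classical estimators", {
  co <- small_cohort(n = 400, seed = 51)
  all_sel <- sample_cch(co, p = 1, pi = 1, seed = 1)
  pd <- phase2_data(co, all_sel)

  ft <- fit_tao_cox(pd, se = FALSE)
  expect_lt(max(abs(ft$coef - fit_cox(co)$coef)), 1e-6)

  fl <- fit_tao_logistic(pd, se = FALSE)
  expect_lt(max(abs(fl$coef - fit_logistic(co)$coef)), 1e-6)

  # conditional table equals the empirical X frequencies per W level (binary X)
  cob <- small_cohort(n = 400, seed = 52)
  cob$x <- as.numeric(cob$x > 0)
  pdb <- phase2_data(cob, sample_cch(cob, p = 1, pi = 1, seed = 1))
  fb <- fit_tao_cox(pdb, w_levels = cob$stratum, se = FALSE)
  emp <- prop.table(table(cob$x, cob$stratum), margin = 2)
  expect_lt(max(abs(fb$nuisance$p_xw - emp)), 1e-8)
})

test_that("EM log-likelihood path is monotone and the table stays a simplex", {
  co <- small_cohort(n = 600, seed = 53)
  sel <- sample_secc(co, n_cases = 40, n_controls = 40, seed = 4)
  pd <- phase2_data(co, sel)
  for (f in list(fit_tao_cox(pd, se = FALSE),
                 fit_tao_logistic(pd, se = FALSE))) {
    expect_true(all(diff(f$ll_trace) >= -1e-6 * (abs(f$loglik) + 1)))
    expect_true(all(abs(colSums(f$nuisance$p_xw) - 1) < 1e-10))
    expect_true(all(f$nuisance$p_xw >= 0))
    expect_true(f$converged)
  }
})

test_that("acceleration reaches the same maximizer as plain EM", {
  co <- small_cohort(n = 500, seed = 54)
  sel <- sample_secc(co, n_cases = 40, n_controls = 40, seed = 6)
  pd <- phase2_data(co, sel)
  fa <- fit_tao_logistic(pd, se = FALSE)
  fp <- fit_tao_logistic(pd, se = FALSE, accelerate = FALSE, max_iter = 2000L)
  expect_lt(abs(fa$coef[["x"]] - fp$coef[["x"]]), 1e-4)
  expect_lt(abs(fa$loglik - fp$loglik), 1e-4 * abs(fa$loglik))
})

test_that("TaoCox recovers the hazard ratio under extreme-control selection", {
  # binary expensive covariate, rare events, SECC with 100 + 100 selected
  s <- rare_setting(x_dist = "binary")
  est <- vapply(1:200, function(r) {
    co <- simulate_cohort(s, seed = 7000 + r)
    sel <- sample_secc(co, n_cases = 100, n_controls = 100, seed = 7000 + r)
    f <- fit_tao_cox(phase2_data(co, sel), se = FALSE)
    if (f$converged) f$coef[["x"]] else NA_real_
  }, 0)
  expect_lt(mean(is.na(est)), 0.05)
  expect_lt(abs(mean(est, na.rm = TRUE) - log(2)), 0.07)
})

test_that("profile-likelihood curvature gives exact and stable standard errors", {
  # quadratic objective: exact closed form
  expect_equal(as.numeric(profile_se(function(b) -(b - 1)^2 / (2 * 0.25),
                                     at = 1)), 0.5, tolerance = 1e-8)
  # Richardson-style stability on a smooth non-quadratic objective
  obj <- function(b) -cosh(b - 0.3)
  s1 <- as.numeric(profile_se(obj, at = 0.3, step = 0.05))
  s2 <- as.numeric(profile_se(obj, at = 0.3, step = 0.025))
  expect_lt(abs(s1 / s2 - 1), 0.01)
  # persistently non-negative curvature is flagged, not fatal
  flat <- profile_se(function(b) 0 * b, at = 0, step = 0.1)
  expect_true(is.na(flat))
  # complete-data profile se agrees with the inverse-information se
  co <- small_cohort(n = 400, seed = 55)
  pd <- phase2_data(co, sample_cch(co, p = 1, pi = 1, seed = 1))
  ft <- fit_tao_cox(pd)
  expect_lt(abs(ft$se[["x"]] / fit_cox(co)$se[["x"]] - 1), 0.05)
})

test_that("matched phase-1 covariate: phase-2 logistic misses it, the EM recovers it", {
  # selection matched on a binary phase-1 covariate (MRD-like): the covariate
  # is balanced between phase-2 cases and controls, so phase-2-only logistic
  # regression cannot see its effect; the semiparametric fit uses the phase-1
  # data of everyone and recovers the full-cohort estimate.
  set.seed(61)
  n <- 3000
  beta_m <- log(2.5)
  base <- sim_setting(gamma = 1, beta_w = beta_m, beta_x = log(1.5), rho = 0.3,
                      target_case_prop = 0.12, n_cohort = n)
  reps <- 20
  lg_m <- tao_m <- full_m <- tao_p <- numeric(reps)
  for (r in 1:reps) {
    co <- with_seed <- NULL
    set.seed(8000 + r)
    mcov <- rbinom(n, 1, 0.3)
    xlat <- 0.3 * scale(mcov)[, 1] + sqrt(1 - 0.09) * rnorm(n)
    u <- runif(n)
    tt <- draw_event_times(base, beta_m * mcov + log(1.5) * xlat, u)
    cen <- runif(n, 0, 1)
    co <- data.frame(id = 1:n, time = pmin(tt, cen),
                     event = as.numeric(tt <= cen),
                     w = mcov, x = xlat, stratum = mcov + 1L)
    # matched sampling: equal cases and controls within each level of w
    sel <- sample_scch(co, n_cases = 60, n_controls = 60,
                       allocation = "balanced", seed = 8000 + r)
    sub <- co[sel$selected, ]
    lg_m[r] <- fit_logistic(sub)$coef[["w"]]
    ftao <- fit_tao_logistic(phase2_data(co, sel), se_coefs = "w",
                             tol_beta = 1e-4)
    tao_m[r] <- ftao$coef[["w"]]
    tao_p[r] <- ftao$wald_p[["w"]]
    full_m[r] <- fit_logistic(co)$coef[["w"]]
  }
  # phase-2-only logistic sees a matched covariate: the estimate collapses
  # to a fraction of the full-cohort effect (matching removes the signal)
  expect_lt(abs(mean(lg_m)), 0.4 * abs(mean(full_m)))
  # the EM recovers the full-cohort log odds ratio, with the right sign and
  # significance in most replicates
  expect_lt(abs(mean(tao_m - full_m)), 0.15)
  expect_gt(mean(tao_m), 0.5)
  expect_gt(mean(tao_p < 0.05), 0.8)
})
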