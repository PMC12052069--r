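test_that("CCH: full selection, fixed counts and exact weights", {
  co <- small_cohort()
  sel <- sample_cch(co, p = 1, pi = 1, seed = 1)
  expect_true(all(sel$selected))
  expect_true(all(sel$weight == 1))

  # 100 controls out of 400 -> weight 4 each
  s <- sim_setting(gamma = 1, lam = 0.35, beta_w = 0, beta_x = 0, rho = 0,
                   n_cohort = 700, n_case_sample = 50, n_control_sample = 100,
                   censor_time = 1, accrual = 0)
  co2 <- simulate_cohort(s, seed = 2)
  ctrl <- which(co2$event == 0)
  co2 <- co2[c(which(co2$event == 1), ctrl[1:400]), ]  # exactly 400 controls
  sel2 <- sample_cch(co2, n_cases = sum(co2$event), n_controls = 100, seed = 3)
  picked <- sel2$selected & co2$event == 0
  expect_equal(sum(picked), 100)
  expect_true(all(sel2$weight[picked] == 4))
  # fixed-count Horvitz-Thompson totals are exact
  expect_equal(sum(sel2$weight[picked]), 400)
})

test_that("Bernoulli CCH weights are Horvitz-Thompson unbiased", {
  co <- small_cohort(n = 600, seed = 11)
  n_ctrl <- sum(co$event == 0)
  tot <- replicate(1000, {
    sel <- sample_cch(co, p = 0.5, pi = 0.3, fixed_count = FALSE)
    sum(sel$weight[sel$selected & co$event == 0])
  })
  expect_lt(abs(mean(tot) / n_ctrl - 1), 0.01)
})

test_that("SCCH: stratum-specific sampling and weights", {
  co <- small_cohort(n = 800, seed = 13)
  # Bernoulli with stratum-specific control proportions
  sel <- sample_scch(co, p_by_stratum = 1, pi_by_stratum = c(0.5, 0.1),
                     fixed_count = FALSE, seed = 5)
  w2 <- sel$weight[sel$selected & co$event == 0 & co$stratum == 2]
  expect_true(all(w2 == 10))
  w1 <- sel$weight[sel$selected & co$event == 0 & co$stratum == 1]
  expect_true(all(w1 == 2))

  # single stratum reduces to CCH-type counts and weights
  co1 <- co; co1$stratum <- 1L
  sel1 <- sample_scch(co1, n_cases = 30, n_controls = 30, seed = 6)
  expect_equal(sum(sel1$selected & co1$event == 1), 30)
  expect_equal(unname(unique(sel1$weight[sel1$selected & co1$event == 1])),
               sum(co1$event == 1) / 30)

  # stratum-wise HT recovery over resamples (fixed-count is exact)
  ht <- replicate(50, {
    s <- sample_scch(co, n_cases = 40, n_controls = 40)
    vapply(1:2, function(k)
      sum(s$weight[s$selected & co$event == 0 & co$stratum == k]), 0)
  })
  truth <- vapply(1:2, function(k) sum(co$event == 0 & co$stratum == k), 0)
  expect_lt(max(abs(rowMeans(ht) / truth - 1)), 0.02)
})

test_that("SECC restricts the control pool by the follow-up threshold", {
  co <- small_cohort(n = 1000, seed = 17)
  # tau = 0 is vacuous: same pools as SCCH
  sel0 <- sample_secc(co, n_cases = 40, n_controls = 40, tau = 0, seed = 4)
  expect_equal(sum(sel0$selected), 80)
  tau9 <- stats::quantile(co$time[co$event == 0], 0.9)
  sel9 <- sample_secc(co, n_cases = 10, n_controls = 10, tau = tau9, seed = 4)
  expect_true(min(co$time[sel9$selected & co$event == 0]) > tau9)
  # default tau: median control follow-up; invariant holds on every draw
  seld <- sample_secc(co, n_cases = 40, n_controls = 40, seed = 8)
  expect_true(min(co$time[seld$selected & co$event == 0]) > seld$tau)
  # empty eligible pool is a design error naming the stratum
  expect_error(sample_secc(co, n_cases = 10, n_controls = 10,
                           tau = max(co$time) + 1, seed = 1),
               "design error")
})

test_that("martingale residuals satisfy the Breslow score identity and bounds", {
  co <- small_cohort(n = 500, seed = 19)
  m <- martingale_residuals(co)
  expect_lt(abs(sum(m)), 1e-6)
  expect_true(all(m <= 1))
  # a censored subject with time near 0 has residual near 0
  co2 <- rbind(co, co[1, ])
  co2$time[nrow(co2)] <- 1e-9
  co2$event[nrow(co2)] <- 0
  m2 <- martingale_residuals(co2)
  expect_lt(abs(m2[nrow(co2)]), 1e-8)
})

test_that("Opt grid search matches brute-force enumeration", {
  # forced allocation: single stratum, budget = 2 * min(#cases, #controls)
  co <- small_cohort(n = 200, seed = 23)
  co$stratum <- 1L
  nmin <- min(sum(co$event), sum(1 - co$event))
  sel <- sample_opt(co, budget = 2 * nmin)
  expect_equal(unname(sel$n_per_stratum[1, ]), c(nmin, nmin))

  # constructed two-strata case: all extreme residuals in stratum 1
  m <- c(0.9, 0.8, -0.9, -0.8, 0.2, 0.1, -0.2, -0.1)
  co2 <- data.frame(id = 1:8, time = 1:8,
                    event = c(1, 1, 0, 0, 1, 1, 0, 0),
                    w = 0, x = 0, stratum = c(1, 1, 1, 1, 2, 2, 2, 2))
  sel2 <- sample_opt(co2, budget = 4, residuals = m)
  expect_equal(unname(sel2$n_per_stratum[, "cases"]), c(2L, 0L))
  expect_equal(which(sel2$selected), 1:4)

  # brute-force oracle over random cohorts, S in {2, 3}, budget <= 20
  for (S in 2:3) {
    set.seed(100 + S)
    co3 <- small_cohort(n = 240, seed = 100 + S)
    co3$stratum <- make_strata(co3$w, S)
    mres <- martingale_residuals(co3)
    sel3 <- sample_opt(co3, budget = 20, residuals = mres)
    # enumerate every allocation independently of the implementation
    combos <- expand.grid(rep(list(0:10), S))
    combos <- combos[rowSums(combos) == 10, , drop = FALSE]
    objs <- apply(combos, 1, function(a) {
      tot <- 0
      ok <- TRUE
      for (k in seq_len(S)) {
        ck <- sort(mres[co3$event == 1 & co3$stratum == k], decreasing = TRUE)
        ok_k <- sort(mres[co3$event == 0 & co3$stratum == k])
        if (a[k] > length(ck) || a[k] > length(ok_k)) ok <- FALSE
        else if (a[k] > 0)
          tot <- tot + sum(ck[seq_len(a[k])]^2) + sum(ok_k[seq_len(a[k])]^2)
      }
      if (ok) tot else -Inf
    })
    expect_equal(sel3$objective, max(objs), tolerance = 1e-10)
  }
})

test_that("Opt respects the grid, caps and degenerate budgets", {
  co <- small_cohort(n = 300, seed = 29)
  sel5 <- sample_opt(co, budget = 40, grid_step = 5)
  expect_true(all(sel5$n_per_stratum %% 5 == 0))
  expect_equal(sum(sel5$selected), 40)
  expect_error(sample_opt(co, budget = 41), "even")
  expect_error(sample_opt(co, budget = 2 * nrow(co) + 2), "even|budget")
  # a balanced-only allocation grid reduces to stratum-balanced
  # extreme sampling
  selb <- sample_opt(co, budget = 40, allocations = matrix(c(10, 10), 1))
  expect_equal(unname(selb$n_per_stratum[, "cases"]), c(10L, 10L))
  # infeasible allocations are a design error
  expect_error(sample_opt(co, budget = 40,
                          allocations = matrix(c(40, 40), 1)),
               "design error")
})

test_that("samplers are deterministic given seed and hit exact budgets", {
  co <- small_cohort(n = 600, seed = 31)
  for (f in list(function(s) sample_cch(co, n_cases = 30, n_controls = 30,
                                        seed = s),
                 function(s) sample_scch(co, n_cases = 30, n_controls = 30,
                                         seed = s),
                 function(s) sample_secc(co, n_cases = 30, n_controls = 30,
                                         seed = s))) {
    a <- f(99)
    b <- f(99)
    expect_identical(a$selected, b$selected)
    expect_equal(sum(a$selected), 60)
  }
  o1 <- sample_opt(co, budget = 60)
  o2 <- sample_opt(co, budget = 60)
  expect_identical(o1$selected, o2$selected)
})

test_that("phase-2 view masks the expensive covariate for unselected subjects", {
  co <- small_cohort()
  sel <- sample_cch(co, n_cases = 20, n_controls = 20, seed = 3)
  pd <- phase2_data(co, sel)
  expect_true(all(is.na(pd$x[!pd$selected])))
  expect_identical(pd$x[pd$selected], co$x[sel$selected])
  expect_identical(pd$weight[pd$selected], sel$weight[sel$selected])
})
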