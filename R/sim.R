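#' Define a simulation setting for a two-phase survival study
#'
#' Bundles the parameters of the Weibull proportional-hazards cohort generator
#' with the phase-2 sampling budget. Event times follow the hazard
#' \eqn{h(t) = \gamma \lambda t^{\gamma - 1} e^{z'\beta}} with survival
#' \eqn{S(t) = \exp(-\lambda t^{\gamma} e^{z'\beta})}, where
#' \eqn{z = (W, X)} holds one inexpensive covariate \eqn{W} (measured on the
#' whole cohort) and one expensive covariate \eqn{X} (measured only on the
#' phase-2 subset). Censoring is administrative at horizon `censor_time` with
#' uniform staggered entry over the last `accrual` fraction of the horizon, so
#' subject-level censoring times are
#' \eqn{C \sim U((1-a)\,c, c)}; `accrual = 0` gives a common fixed horizon.
#'
#' Either `lam` or `target_case_prop` must be supplied; in the latter case the
#' Weibull scale is calibrated with [calibrate_scale()] so that the expected
#' event (case) proportion matches the target.
#'
#' @param gamma Weibull shape (> 0).
#' @param lam Weibull scale \eqn{\lambda} (> 0), or `NULL` to calibrate.
#' @param beta_w Log hazard ratio of the inexpensive covariate.
#' @param beta_x Log hazard ratio of the expensive covariate.
#' @param rho Correlation between `W` and `X` in \[-1, 1\]; 0 gives the
#'   independent scenario, the default 0.5 the correlated scenario.
#' @param n_cohort Full cohort size.
#' @param n_case_sample,n_control_sample Phase-2 budget per arm.
#' @param censor_time Administrative censoring horizon (> 0, may be `Inf`).
#' @param accrual Fraction of the horizon over which entry is uniformly
#'   staggered, in \[0, 1\].
#' @param target_case_prop Optional expected case proportion used to calibrate
#'   `lam` when `lam` is `NULL`.
#' @param x_dist Distribution of the expensive covariate: `"normal"`
#'   (standard normal, correlated with `W` through a Gaussian copula) or
#'   `"binary"` (indicator that the latent correlated normal exceeds 0).
#' @param n_strata Number of strata cut from `W` (quantile bins).
#' @param n_reps Default replicate count for [run_experiment()].
#' @param seed Default RNG seed for [simulate_cohort()].
#'
#' @return An object of class `sim_setting`.
#' @examples
#' s <- sim_setting(gamma = 1, lam = 1, beta_w = 0, beta_x = 0, censor_time = 1)
#' cohort <- simulate_cohort(s, seed = 1)
#' mean(cohort$event)
#' @export
sim_setting <- function(gamma = 0.3, lam = NULL, beta_w = log(2), beta_x = log(2),
                        rho = 0.5, n_cohort = 3000L, n_case_sample = 100L,
                        n_control_sample = 100L, censor_time = 1,
                        accrual = 1, target_case_prop = NULL,
                        x_dist = c("normal", "binary"), n_strata = 2L,
                        n_reps = 500L, seed = 1L) {
  x_dist <- match.arg(x_dist)
  if (!is.numeric(gamma) || gamma <= 0) stop("parameter error: gamma must be > 0")
  if (!is.null(lam) && lam <= 0) stop("parameter error: lam must be > 0")
  if (abs(rho) > 1) stop("parameter error: |rho| must be <= 1")
  if (censor_time <= 0) stop("parameter error: censor_time must be > 0")
  if (accrual < 0 || accrual > 1) stop("parameter error: accrual must be in [0, 1]")
  if (n_case_sample + n_control_sample > n_cohort)
    stop("parameter error: phase-2 budget exceeds cohort size")
  if (n_reps < 1) stop("parameter error: n_reps must be >= 1")
  s <- structure(list(
    gamma = gamma, lam = lam, beta_w = beta_w, beta_x = beta_x, rho = rho,
    n_cohort = as.integer(n_cohort), n_case_sample = as.integer(n_case_sample),
    n_control_sample = as.integer(n_control_sample), censor_time = censor_time,
    accrual = accrual, target_case_prop = target_case_prop, x_dist = x_dist,
    n_strata = as.integer(n_strata), n_reps = as.integer(n_reps),
    seed = as.integer(seed)), class = "sim_setting")
  if (is.null(lam)) {
    if (is.null(target_case_prop))
      stop("parameter error: supply either lam or target_case_prop")
    s$lam <- calibrate_scale(gamma, beta_w, beta_x, rho, censor_time,
                             target_case_prop, x_dist = x_dist,
                             accrual = accrual)
  }
  s
}

#' @export
print.sim_setting <- function(x, ...) {
  cat("Two-phase simulation setting\n")
  cat(sprintf("  Weibull shape %.3g, scale %.4g; beta_w = %.3f, beta_x = %.3f, rho = %.2f\n",
              x$gamma, x$lam, x$beta_w, x$beta_x, x$rho))
  cat(sprintf("  cohort n = %d; phase-2 budget %d cases + %d controls\n",
              x$n_cohort, x$n_case_sample, x$n_control_sample))
  cat(sprintf("  censoring horizon %.3g (accrual fraction %.2f); X %s; %d strata\n",
              x$censor_time, x$accrual, x$x_dist, x$n_strata))
  if (!is.null(x$target_case_prop))
    cat(sprintf("  scale calibrated to case proportion %.3f\n", x$target_case_prop))
  invisible(x)
}

#' Expected case proportion under a simulation setting
#'
#' Computes \eqn{P(\delta = 1) = E[P(T \le C \mid W, X)]} by Gauss-Legendre
#' quadrature over the covariate linear predictor and the censoring-time
#' distribution, without simulation.
#'
#' @param setting A [sim_setting()].
#' @param lam Weibull scale to evaluate at (defaults to the setting's).
#' @return Scalar event probability.
#' @export
expected_case_prop <- function(setting, lam = setting$lam) {
  g <- setting$gamma
  c0 <- setting$censor_time
  a <- setting$accrual
  if (is.infinite(c0)) return(1)
  # P(T <= C | v) averaged over C ~ U((1-a)c0, c0), v the linear predictor
  p_event_v <- function(v) {
    if (a <= 0) return(1 - exp(-lam * c0^g * exp(v)))
    lo <- (1 - a) * c0
    gl <- gauss_legendre(48L)
    tt <- (gl$nodes + 1) / 2 * (c0 - lo) + lo
    wt <- gl$weights / 2
    vapply(v, function(vi) sum(wt * (1 - exp(-lam * tt^g * exp(vi)))), 0)
  }
  if (setting$x_dist == "normal") {
    s2 <- setting$beta_w^2 + setting$beta_x^2 +
      2 * setting$rho * setting$beta_w * setting$beta_x
    if (s2 < 1e-14) return(p_event_v(0))
    s <- sqrt(s2)
    gl <- gauss_legendre(96L)
    v <- gl$nodes * 8 * s
    wt <- gl$weights * 8 * s * stats::dnorm(v, sd = s)
    sum(wt * p_event_v(v))
  } else {
    gl <- gauss_legendre(96L)
    w <- gl$nodes * 8
    wt <- gl$weights * 8 * stats::dnorm(w)
    px1 <- if (abs(setting$rho) == 1) as.numeric(setting$rho * w > 0) else
      stats::pnorm(setting$rho * w / sqrt(1 - setting$rho^2))
    sum(wt * (px1 * p_event_v(setting$beta_w * w + setting$beta_x) +
                (1 - px1) * p_event_v(setting$beta_w * w)))
  }
}

#' Calibrate the Weibull scale to a target case proportion
#'
#' Finds \eqn{\lambda} such that the expected event proportion of the cohort
#' generator equals `target_case_prop`, by root finding on the numeric
#' integral computed by [expected_case_prop()].
#'
#' @inheritParams sim_setting
#' @param target_case_prop Target event proportion in (0, 1).
#' @return The calibrated scale \eqn{\lambda}.
#' @examples
#' # exponential baseline, no covariate effect, fixed horizon 1:
#' # P(T <= 1) = 1 - exp(-lam), so a 10% target gives lam = -log(0.9)
#' calibrate_scale(1, 0, 0, 0, 1, 0.10, accrual = 0)
#' @export
calibrate_scale <- function(gamma, beta_w, beta_x, rho, censor_time,
                            target_case_prop, x_dist = "normal", accrual = 1) {
  if (!is.numeric(target_case_prop) || target_case_prop <= 0 || target_case_prop >= 1)
    stop("infeasibility error: target_case_prop must be in (0, 1)")
  if (is.infinite(censor_time))
    stop("infeasibility error: case proportion is 1 without censoring")
  proto <- structure(list(gamma = gamma, lam = 1, beta_w = beta_w,
                          beta_x = beta_x, rho = rho, censor_time = censor_time,
                          accrual = accrual, x_dist = x_dist),
                     class = "sim_setting")
  f <- function(loglam) expected_case_prop(proto, lam = exp(loglam)) - target_case_prop
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    stop("infeasibility error: target case proportion not attainable")
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-10)
  exp(r$root)
}

#' Draw latent Weibull proportional-hazards event times
#'
#' Inverse-transform sampling:
#' \eqn{T = (-\log U / (\lambda e^{z'\beta}))^{1/\gamma}} with
#' \eqn{U \sim U(0,1)}, so that \eqn{S(t \mid z) = \exp(-\lambda t^\gamma e^{z'\beta})}.
#'
#' @param setting A [sim_setting()] (only `gamma` and `lam` are used).
#' @param lp Per-subject linear predictor \eqn{z'\beta}.
#' @param u Optional uniform draws (for reproducibility or exact checks);
#'   defaults to `runif(length(lp))`.
#' @return Vector of latent event times.
#' @examples
#' s <- sim_setting(gamma = 1, lam = 1, beta_w = 0, beta_x = 0, censor_time = 1)
#' draw_event_times(s, lp = 0, u = exp(-2))  # exactly 2
#' @export
draw_event_times <- function(setting, lp, u = NULL) {
  if (setting$gamma <= 0 || setting$lam <= 0)
    stop("parameter error: gamma and lam must be > 0")
  if (any(!is.finite(lp))) stop("parameter error: linear predictor must be finite")
  u <- u %||% stats::runif(length(lp))
  (-log(u) / (setting$lam * exp(lp)))^(1 / setting$gamma)
}

#' Simulate a full two-phase cohort
#'
#' Draws the inexpensive covariate \eqn{W \sim N(0,1)}, the expensive
#' covariate \eqn{X = \rho W + \sqrt{1-\rho^2}\,\epsilon} (thresholded at 0
#' for `x_dist = "binary"`), latent event times from the Weibull
#' proportional-hazards model, and censoring times from the staggered-entry
#' mechanism of the setting. Strata are quantile bins of `W`.
#'
#' @param setting A [sim_setting()].
#' @param seed RNG seed (defaults to the setting's seed). Two calls with the
#'   same seed produce identical cohorts.
#' @return A `data.frame` of class `cohort` with columns `id`, `time`,
#'   `event`, `w`, `x`, `stratum`.
#' @export
simulate_cohort <- function(setting, seed = setting$seed) {
  stopifnot(inherits(setting, "sim_setting"))
  n <- setting$n_cohort
  out <- with_seed(seed, {
    w <- stats::rnorm(n)
    eps <- stats::rnorm(n)
    xlat <- setting$rho * w + sqrt(1 - setting$rho^2) * eps
    x <- if (setting$x_dist == "binary") as.numeric(xlat > 0) else xlat
    u <- stats::runif(n)
    tt <- draw_event_times(setting, setting$beta_w * w + setting$beta_x * x, u)
    cen <- if (is.infinite(setting$censor_time)) rep(Inf, n)
      else if (setting$accrual > 0)
        stats::runif(n, (1 - setting$accrual) * setting$censor_time,
                     setting$censor_time)
      else rep(setting$censor_time, n)
    list(w = w, x = x, tt = tt, cen = cen)
  })
  time <- pmin(out$tt, out$cen)
  event <- as.numeric(out$tt <= out$cen)
  df <- data.frame(id = seq_len(n), time = time, event = event,
                   w = out$w, x = out$x,
                   stratum = make_strata(out$w, setting$n_strata))
  attr(df, "setting") <- setting
  class(df) <- c("cohort", "data.frame")
  df
}

#' Cut a phase-1 covariate into strata
#'
#' Quantile (equal-frequency) bins; a covariate with at most `n_bins` distinct
#' values (e.g. binary) yields its natural categories. Labels are `1..S` with
#' no empty stratum.
#'
#' @param w Numeric covariate vector.
#' @param n_bins Number of strata requested.
#' @return Integer stratum labels.
#' @export
make_strata <- function(w, n_bins = 2L) {
  ux <- unique(w)
  if (length(ux) <= n_bins) return(as.integer(factor(w)))
  br <- unique(stats::quantile(w, probs = seq(0, 1, length.out = n_bins + 1)))
  as.integer(cut(w, breaks = br, include.lowest = TRUE, labels = FALSE))
}
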