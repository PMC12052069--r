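#' @title Fit-result container
#' @description All estimators return a `twophase_fit`: coefficient estimates
#'   (log hazard ratios for the Cox family, log odds ratios for the logistic
#'   family), standard errors, covariance, 95% Wald intervals
#'   (`coef +/- 1.96 se` on the log scale), two-sided Wald p-values, the
#'   maximized (pseudo-)log-likelihood, and convergence diagnostics.
#' @keywords internal
new_twophase_fit <- function(method_label, coef, se, cov, loglik, converged,
                             n_iter, n_used, nuisance = NULL, ll_trace = NULL,
                             variance_failure = FALSE) {
  se <- se[names(coef)]
  names(se) <- names(coef)
  ci95 <- cbind(lower = coef - 1.96 * se, upper = coef + 1.96 * se)
  z <- coef / se
  structure(list(method_label = method_label, coef = coef, se = se, cov = cov,
                 ci95 = ci95, wald_p = 2 * stats::pnorm(-abs(z)),
                 loglik = loglik, converged = converged, n_iter = n_iter,
                 n_used = n_used, nuisance = nuisance, ll_trace = ll_trace,
                 variance_failure = variance_failure),
            class = "twophase_fit")
}

#' Cox regression (unweighted or design-weighted) on phase-2 data
#'
#' Maximizes the Breslow-tie Cox partial likelihood via [survival::coxph()].
#' With design `weights` the partial likelihood is weight-multiplied and the
#' variance is the robust (Lin-Ying style) sandwich aggregating per-subject
#' score residuals; without weights the variance is the inverse information.
#' Monotone likelihood (separation) is reported through `converged = FALSE`,
#' not an exception.
#'
#' @param data A `data.frame` with columns `time`, `event` and the covariates
#'   (typically the phase-2 subset of a cohort).
#' @param covariates Covariate column names.
#' @param weights Optional design weights (e.g. from a `phase2_selection`).
#' @return A [`twophase_fit`][new_twophase_fit] labelled `"Cox"` or `"CoxW"`.
#' @examples
#' d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0), z = c(1, 0, 1))
#' fit_cox(d, "z")$coef  # closed form: exp(beta) = 1/sqrt(2)
#' @export
fit_cox <- function(data, covariates = c("w", "x"), weights = NULL) {
  if (!all(c("time", "event") %in% names(data)))
    stop("data must contain time and event columns")
  if (sum(data$event) < 1) stop("estimation error: no events")
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(covariates, collapse = " + ")))
  environment(f) <- environment()
  robust <- !is.null(weights)
  bad <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(f, data = data, weights = weights, ties = "breslow",
                    robust = robust,
                    control = survival::coxph.control(timefix = FALSE)),
    warning = function(w) {
      if (grepl("converge|infinite|out of iterations|beta may be",
                conditionMessage(w))) {
        bad <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- stats::coef(fit)
  if (any(is.na(cf)))
    stop("estimation error: singular information (rank-deficient covariates)")
  V <- stats::vcov(fit)  # robust sandwich when weights are present
  new_twophase_fit(if (robust) "CoxW" else "Cox", cf, sqrt(diag(V)), V,
                   loglik = fit$loglik[2], converged = !bad,
                   n_iter = fit$iter, n_used = fit$n)
}

#' Logistic regression of event status on phase-2 data
#'
#' Maximum likelihood via IRLS ([stats::glm()]). Coefficients are log odds
#' ratios; the intercept is reported but carries no design meaning under
#' outcome-dependent sampling. Perfect separation is reported through
#' `converged = FALSE`.
#'
#' @inheritParams fit_cox
#' @return A [`twophase_fit`][new_twophase_fit] labelled `"LG"`.
#' @export
fit_logistic <- function(data, covariates = c("w", "x")) {
  if (length(unique(data$event)) < 2)
    stop("estimation error: both outcome classes must be present")
  f <- stats::reformulate(covariates, response = "event")
  environment(f) <- environment()
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- stats::coef(fit)
  if (any(is.na(cf)))
    stop("rank error: constant or collinear covariate")
  V <- stats::vcov(fit)
  new_twophase_fit("LG", cf, sqrt(diag(V)), V,
                   loglik = as.numeric(stats::logLik(fit)),
                   converged = fit$converged && !sep,
                   n_iter = fit$iter, n_used = nrow(data))
}

#' Two-sided Wald test of a single coefficient
#'
#' @param fit A converged `twophase_fit`.
#' @param coef_name Coefficient to test.
#' @param alpha Significance level.
#' @return A list with `reject`, `p`, `z`, `alpha`;
#'   \eqn{p = 2(1 - \Phi(|\hat\beta/\widehat{se}|))}.
#' @export
wald_test <- function(fit, coef_name, alpha = 0.05) {
  stopifnot(inherits(fit, "twophase_fit"))
  if (!fit$converged) stop("estimation error: fit did not converge")
  if (!coef_name %in% names(fit$coef))
    stop(sprintf("key error: no coefficient named '%s'", coef_name))
  b <- fit$coef[[coef_name]]
  s <- fit$se[[coef_name]]
  z <- if (b == 0) 0 else b / s
  p <- 2 * stats::pnorm(-abs(z))
  list(reject = p < alpha, p = p, z = z, alpha = alpha)
}

#' Fit a two-phase analysis method
#'
#' Single entry point dispatching to the package's estimators:
#' `"cox"` (full-data Cox), `"coxw"` (design-weighted Cox with robust
#' variance), `"logistic"` (phase-2 logistic regression), `"tao_cox"` /
#' `"tao_logistic"` (semiparametric maximum likelihood combining phase-1 and
#' phase-2 data; see [fit_tao_cox()]).
#'
#' @param data For `cox`/`coxw`/`logistic`: the analysis rows (full cohort or
#'   phase-2 subset). For the semiparametric methods: a phase-1 + phase-2 view
#'   as produced by [phase2_data()].
#' @param method Analysis method.
#' @param covariates Covariate column names (expensive covariate included).
#' @param weights Design weights for `coxw`; defaults to the `weight` column.
#' @param ... Passed on to the underlying fitter.
#' @return A `twophase_fit`.
#' @export
fit_twophase <- function(data,
                         method = c("cox", "coxw", "logistic", "tao_cox",
                                    "tao_logistic"),
                         covariates = c("w", "x"), weights = NULL, ...) {
  method <- match.arg(method)
  switch(method,
    cox = fit_cox(data, covariates, ...),
    coxw = fit_cox(data, covariates,
                   weights = weights %||% data$weight, ...),
    logistic = fit_logistic(data, covariates, ...),
    tao_cox = fit_tao_cox(data, covariates, ...),
    tao_logistic = fit_tao_logistic(data, covariates, ...))
}

#' @export
print.twophase_fit <- function(x, ...) {
  cat(sprintf("<twophase_fit: %s>  n = %d, loglik = %.4f, %s (%d iter)\n",
              x$method_label, x$n_used, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(summary(x)$table, digits = 4)
  invisible(x)
}

#' @export
summary.twophase_fit <- function(object, ...) {
  tab <- data.frame(term = names(object$coef),
                    estimate = unname(object$coef),
                    exp_estimate = exp(unname(object$coef)),
                    se = unname(object$se),
                    lower = unname(object$ci95[, "lower"]),
                    upper = unname(object$ci95[, "upper"]),
                    p = unname(object$wald_p),
                    row.names = NULL)
  out <- list(method_label = object$method_label, table = tab,
              loglik = object$loglik, converged = object$converged,
              n_used = object$n_used)
  class(out) <- "summary.twophase_fit"
  out
}

#' @export
print.summary.twophase_fit <- function(x, ...) {
  cat(sprintf("Method: %s (n = %d)\n", x$method_label, x$n_used))
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
coef.twophase_fit <- function(object, ...) object$coef

#' @export
vcov.twophase_fit <- function(object, ...) object$cov

#' @export
confint.twophase_fit <- function(object, parm, level = 0.95, ...) {
  q <- stats::qnorm((1 + level) / 2)
  ci <- cbind(object$coef - q * object$se, object$coef + q * object$se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, (1 + level) / 2),
                               trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Tidy coefficient table of a fit
#'
#' @param fit A `twophase_fit`.
#' @return A `data.frame` with columns `term`, `estimate`, `exp_estimate`
#'   (odds/hazard ratio), `se`, `lower`, `upper`, `p`.
#' @export
tidy_fit <- function(fit) summary(fit)$table
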