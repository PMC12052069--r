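# Semiparametric maximum likelihood for two-phase data: the expensive
# covariate X is observed only for phase-2 subjects (R = 1); for R = 0 the
# likelihood sums over a finite support of X with a model for P(X | W).
# Valid for any phase-2 selection that depends only on phase-1 observables
# (t, delta, W) -- a documented contract that the fitter cannot check.
#
# P(X = x_j | W) is a multinomial-logit sieve softmax_j(theta_j' B(W)) with
# a polynomial basis B(W) = (1, w, w^2) by default. The smooth-in-w
# conditional model matters:
# a conditional table on coarse W levels breaks down under designs whose
# selection varies with W inside a level (the extreme-residual optimal
# design), visibly biasing the estimate of the expensive-covariate effect and
# inflating type I error. Passing explicit `w_levels` switches to the
# classical per-level table (the saturated, piecewise-constant special case).
#
# The EM map is a function of the posterior support weights q of the
# unselected subjects, so the fixed-point iteration is accelerated by SQUAREM
# extrapolation on q with an adaptive step cap; an extrapolated point is
# accepted only when the observed-data log-likelihood (computed exactly after
# the following M-step) does not decrease, so the recorded likelihood path
# stays monotone.

# shared preprocessing for both outcome models
tao_prepare <- function(data, covariates, x_col, n_bins, w_levels,
                        sieve_degree = 2L) {
  if (!x_col %in% covariates)
    stop(sprintf("x_col '%s' must be among the covariates", x_col))
  n <- nrow(data)
  R <- if (!is.null(data$selected)) as.logical(data$selected)
       else !is.na(data[[x_col]])
  if (any(R & is.na(data[[x_col]])))
    stop("X must be observed for every selected subject")
  if (any(!R & !is.na(data[[x_col]])))
    stop("X must be missing for every unselected subject (mask with phase2_data)")
  if (!any(R)) stop("estimation error: no phase-2 subjects")
  wcovs <- setdiff(covariates, x_col)
  i1 <- which(R)
  i0 <- which(!R)
  xobs <- data[[x_col]][i1]
  ux <- sort(unique(xobs))
  if (length(ux) > n_bins) {
    br <- unique(stats::quantile(xobs, probs = seq(0, 1, length.out = n_bins + 1)))
    bins <- cut(xobs, breaks = br, include.lowest = TRUE, labels = FALSE)
    support <- as.numeric(tapply(xobs, bins, mean))
  } else {
    support <- ux
    bins <- match(xobs, ux)
  }
  m <- length(support)
  if (m < 2) stop("estimation error: X support must contain at least 2 values")
  # conditional-model structure for P(X | W)
  if (!is.null(w_levels)) {
    lev <- as.integer(factor(w_levels))
    L <- max(lev)
    tab1 <- unclass(table(factor(bins, levels = seq_len(m)),
                          factor(lev[i1], levels = seq_len(L))))
    nmod <- list(kind = "table", lev = lev, L = L, tab1 = tab1)
  } else {
    # smooth sieve: multinomial logit in a polynomial of the first phase-1
    # covariate (standardized); with no W covariate this is the marginal
    # distribution
    Bw <- if (length(wcovs)) {
      w1 <- data[[wcovs[1]]]
      du <- length(unique(w1))
      if (du > 1) {
        ws <- (w1 - mean(w1)) / stats::sd(w1)
        deg <- min(as.integer(sieve_degree), du - 1L)
        do.call(cbind, c(list(rep(1, n)), lapply(seq_len(deg),
                                                 function(k) ws^k)))
      } else matrix(1, n, 1)
    } else matrix(1, n, 1)
    d <- ncol(Bw)
    momidx <- matrix(0L, d, d)
    idx <- 0L
    Bmom <- matrix(0, n, d * (d + 1) / 2)
    for (a in seq_len(d)) for (b in a:d) {
      idx <- idx + 1L
      Bmom[, idx] <- Bw[, a] * Bw[, b]
      momidx[a, b] <- momidx[b, a] <- idx
    }
    nmod <- list(kind = "logit", Bw = Bw, d = d, Bmom = Bmom, momidx = momidx)
  }
  # posterior "counts" of the phase-2 subjects are fixed indicator rows
  C1 <- matrix(0, length(i1), m)
  C1[cbind(seq_along(i1), bins)] <- 1
  W <- if (length(wcovs)) as.matrix(data[wcovs]) else matrix(0, n, 0)
  storage.mode(W) <- "double"
  list(n = n, R = R, i1 = i1, i0 = i0, n1 = length(i1), n0 = length(i0),
       wcovs = wcovs, pw = length(wcovs), W = W,
       xobs = xobs, support = support, m = m, bins = bins, C1 = C1,
       nmod = nmod)
}

# log P(X = x_j | W_i) for all subjects (n x m) given nuisance parameters
tao_logP <- function(prep, par) {
  if (prep$nmod$kind == "table") {
    t(log(par))[prep$nmod$lev, , drop = FALSE]
  } else {
    eta <- cbind(0, prep$nmod$Bw %*% t(par))   # n x m, reference column 1
    rmx <- row_max(eta)
    eta - (rmx + log(rowSums(exp(eta - rmx))))
  }
}

# M-step for the conditional model given posterior counts C (n x m rows
# summing to 1): closed-form per-level frequencies for the table model;
# Newton-maximized multinomial logit for the sieve (concave, step-halved,
# warm-started -- full maximization, preserving EM ascent)
tao_pxw_mstep <- function(prep, C, par) {
  m <- prep$m
  if (prep$nmod$kind == "table") {
    L <- prep$nmod$L
    cnt <- matrix(0, m, L)
    for (l in seq_len(L)) {
      rows <- prep$nmod$lev == l
      if (any(rows)) cnt[, l] <- colSums(C[rows, , drop = FALSE])
    }
    p <- sweep(cnt, 2, pmax(colSums(cnt), 1e-300), "/")
    if (any(abs(colSums(p) - 1) > 1e-10))
      stop("internal error: conditional distribution left the simplex")
    return(p)
  }
  B <- prep$nmod$Bw
  d <- prep$nmod$d
  k <- m - 1L
  theta <- par                                  # k x d
  Ck <- C[, -1, drop = FALSE]
  CB <- crossprod(B, Ck)                        # constant within the M-step
  # returns the multinomial log-likelihood and P for a candidate theta
  eval_th <- function(th) {
    etak <- B %*% t(th)                         # n x k (reference column = 0)
    rmx <- pmax(row_max(etak), 0)
    lse <- rmx + log(exp(-rmx) + rowSums(exp(etak - rmx)))
    list(ll = sum(Ck * etak) - sum(lse), P = exp(etak - lse))
  }
  ev <- eval_th(theta)
  ll <- ev$ll
  for (it in 1:12) {
    Pj <- ev$P
    g <- CB - crossprod(B, Pj)                  # d x k
    # negative Hessian blocks via basis moments:
    # H[j,l] = sum_i P_ij (1[j==l] - P_il) b_i b_i'
    nm <- ncol(prep$nmod$Bmom)
    momidx <- prep$nmod$momidx
    # one fused crossprod: column (mo-1)*k + j holds (Pj * bb_mo)' Pj[, l]
    PB <- Pj[, rep(seq_len(k), times = nm), drop = FALSE] *
      prep$nmod$Bmom[, rep(seq_len(nm), each = k), drop = FALSE]
    cross_all <- crossprod(PB, Pj)              # (nm*k) x k
    diag_all <- crossprod(prep$nmod$Bmom, Pj)   # nm x k
    H <- matrix(0, k * d, k * d)
    for (j in seq_len(k)) for (l in j:k) {
      blk <- matrix(0, d, d)
      for (a in seq_len(d)) for (b in seq_len(d)) {
        mo <- momidx[a, b]
        blk[a, b] <- (if (j == l) diag_all[mo, j] else 0) -
          cross_all[(mo - 1L) * k + j, l]
      }
      rj <- (j - 1L) * d + seq_len(d)
      rl <- (l - 1L) * d + seq_len(d)
      H[rj, rl] <- blk
      H[rl, rj] <- t(blk)
    }
    gv <- numeric(k * d)
    for (j in seq_len(k)) gv[(j - 1L) * d + seq_len(d)] <- g[, j]
    step <- tryCatch(solve(H + 1e-8 * diag(k * d), gv),
                     error = function(e) NULL)
    if (is.null(step)) break
    stepm <- matrix(step, d, k)                  # columns j = 2..m
    new_theta <- theta + t(stepm)
    new_ev <- eval_th(new_theta)
    h <- 0L
    while ((!is.finite(new_ev$ll) || new_ev$ll < ll - 1e-12) && h < 25L) {
      stepm <- stepm / 2
      h <- h + 1L
      new_theta <- theta + t(stepm)
      new_ev <- eval_th(new_theta)
    }
    dth <- max(abs(new_theta - theta))
    dll <- abs(new_ev$ll - ll)
    theta <- new_theta
    ev <- new_ev
    ll <- ev$ll
    if (dth < 1e-6 || dll < 1e-12 * (abs(ll) + 1)) break
  }
  theta
}

tao_pxw_init <- function(prep) {
  if (prep$nmod$kind == "table") {
    # light smoothing keeps every support point live in every level
    sweep(prep$nmod$tab1 + 0.5, 2, colSums(prep$nmod$tab1 + 0.5), "/")
  } else {
    matrix(0, prep$m - 1L, prep$nmod$d)
  }
}

# evaluated conditional distribution for reporting
tao_pxw_report <- function(prep, par) {
  if (prep$nmod$kind == "table") {
    structure(par, dimnames = list(signif(prep$support, 6),
                                   paste0("level_", seq_len(prep$nmod$L))))
  } else if (prep$nmod$d == 1L) {
    eta <- cbind(0, matrix(par[, 1], 1))
    p <- exp(eta - max(eta)) / sum(exp(eta - max(eta)))
    structure(t(p), dimnames = list(signif(prep$support, 6), "marginal"))
  } else {
    qs <- stats::quantile(prep$nmod$Bw[, 2], probs = seq(0.05, 0.95, 0.1))
    Bq <- do.call(cbind, c(list(rep(1, 10)),
                           lapply(seq_len(prep$nmod$d - 1L),
                                  function(k) qs^k)))
    eta <- cbind(0, Bq %*% t(par))
    rmx <- row_max(eta)
    p <- exp(eta - (rmx + log(rowSums(exp(eta - rmx)))))
    structure(t(p), dimnames = list(signif(prep$support, 6),
                                    paste0("w_decile_", 1:10)))
  }
}

# Generic accelerated EM driver. `one_iter(q, state)` performs one full EM
# sweep (M-step, then observed log-likelihood and E-step at the new
# parameters) and returns list(beta, ll, q, par, ...). Convergence is judged
# between consecutive plain EM sweeps on the coefficient change and the
# relative log-likelihood change; monotonicity of the accepted
# log-likelihood path is asserted throughout.
tao_em_drive <- function(one_iter, init, n0, iter_cap, tol_beta, tol_ll,
                         accelerate = TRUE) {
  ll_trace <- numeric(0)
  it_total <- 0L
  check <- function(prev_ll, prev_beta, s) {
    if (is.finite(prev_ll) && s$ll < prev_ll - 1e-7 * (abs(prev_ll) + 1))
      stop("internal error: EM observed-data log-likelihood decreased")
    max(abs(s$beta - prev_beta)) < tol_beta &&
      abs(s$ll - prev_ll) < tol_ll * (abs(prev_ll) + 1)
  }
  state <- init
  state$ll <- -Inf
  stepmax <- 4       # adaptive extrapolation cap
  repeat {
    s1 <- one_iter(state$q, state)
    it_total <- it_total + 1L
    ll_trace <- c(ll_trace, s1$ll)
    if (check(state$ll, state$beta, s1) || it_total >= iter_cap)
      return(c(s1, list(iter = it_total, converged = it_total < iter_cap,
                        ll_trace = ll_trace)))
    if (!accelerate || n0 == 0) {
      state <- s1
      next
    }
    s2 <- one_iter(s1$q, s1)
    it_total <- it_total + 1L
    ll_trace <- c(ll_trace, s2$ll)
    if (check(s1$ll, s1$beta, s2) || it_total >= iter_cap)
      return(c(s2, list(iter = it_total, converged = it_total < iter_cap,
                        ll_trace = ll_trace)))
    # SQUAREM extrapolation on the posterior weights, with a monotone guard
    # and an adaptive step cap: grow the cap after a success at the cap,
    # shrink it after a rejected step
    r <- s1$q - state$q
    v <- (s2$q - s1$q) - r
    a2 <- sum(v * v)
    alpha <- if (a2 > 0) -sqrt(sum(r * r) / a2) else -1
    if (!is.finite(alpha)) alpha <- -1
    alpha <- min(max(alpha, -stepmax), -1)
    if (alpha == -1) {
      state <- s2
      next
    }
    qa <- state$q - 2 * alpha * r + alpha^2 * v
    qa[qa < 1e-12] <- 1e-12
    qa <- qa / rowSums(qa)
    s3 <- one_iter(qa, s2)
    it_total <- it_total + 1L
    if (s3$ll >= s2$ll) {
      ll_trace <- c(ll_trace, s3$ll)
      state <- s3
      if (alpha == -stepmax) stepmax <- stepmax * 4
    } else {
      state <- s2
      stepmax <- max(1, stepmax / 4)
    }
  }
}

#' Semiparametric maximum-likelihood Cox fit for two-phase data
#'
#' Maximizes the full likelihood
#' \deqn{\prod_{R=1} f(t,\delta \mid X, W)\,P(X \mid W)\;
#'       \prod_{R=0} \sum_j f(t,\delta \mid x_j, W)\,P(x_j \mid W)}
#' where \eqn{f} is the Cox density
#' \eqn{\lambda(t)^\delta e^{\delta(\beta_x x + \beta_w'W)}
#'      \exp(-\Lambda(t) e^{\beta_x x + \beta_w'W})}
#' with a nonparametric (jump) baseline, and \eqn{P(X = x_j \mid W)} is a
#' multinomial-logit sieve in the first phase-1 covariate over a finite
#' support \eqn{x_1, \ldots, x_m}. Estimation is by EM: the E-step computes
#' posterior support weights \eqn{q_{ij}} for unselected subjects; the M-step
#' updates the conditional model by a weighted multinomial fit (closed-form
#' table or concave Newton sieve) and \eqn{(\beta, \Lambda)} by a weighted
#' Cox fit with Breslow baseline on the support-expanded data. Both M-steps
#' fully maximize, so the observed-data log-likelihood is non-decreasing --
#' asserted at every iteration, including under the SQUAREM acceleration,
#' whose extrapolated steps are accepted only when the observed
#' log-likelihood does not decrease. Standard errors come from the numerical
#' curvature of the profile log-likelihood ([profile_se()]).
#'
#' Continuous X is discretized to `n_bins` equal-frequency bins of the
#' phase-2 observations (support = bin means); binary or categorical X is
#' used as-is. The conditional model must track how X varies with \eqn{W}: a
#' coarse conditional *table* (available via `w_levels`) is enough for
#' selections that are constant within its levels, but visibly biases the
#' expensive-covariate estimate under selection rules that vary with \eqn{W}
#' inside a level (e.g. the extreme-martingale-residual optimal design), so
#' the smooth sieve is the default. Selection must depend only on phase-1
#' observables; this is the caller's contract and is not checkable from the
#' data.
#'
#' @param data Phase-1 + phase-2 view: every cohort row, with `x_col` equal to
#'   `NA` for unselected subjects (see [phase2_data()]). Needs `time`, `event`.
#' @param covariates Covariate names in the outcome model (must include
#'   `x_col`).
#' @param x_col Name of the expensive covariate.
#' @param n_bins Support size for a continuous expensive covariate.
#' @param w_levels Optional explicit conditioning levels: switches
#'   \eqn{P(X|W)} to a per-level conditional probability table (the
#'   saturated, piecewise-constant special case of the sieve).
#' @param sieve_degree Polynomial degree of the sieve basis in the
#'   standardized first phase-1 covariate (default 2; degree 1 is a purely
#'   linear logit trend, which leaves a visible approximation bias under the
#'   extreme-residual optimal design).
#' @param max_iter,tol_beta,tol_ll EM control: stop when the largest
#'   coefficient change is below `tol_beta` and the relative log-likelihood
#'   change is below `tol_ll`, or after `max_iter` iterations.
#' @param se Compute profile-likelihood standard errors?
#' @param se_step Central-difference step for [profile_se()].
#' @param se_coefs Coefficients to compute profile standard errors for
#'   (default: the expensive covariate; others are reported as `NA`).
#' @param accelerate Use monotone-guarded SQUAREM acceleration of the EM
#'   fixed-point iteration (same maximizer, fewer sweeps).
#' @return A `twophase_fit` labelled `"TaoCox"`, with the nuisance model
#'   (support, conditional distribution, baseline jumps) in `$nuisance` and
#'   the EM log-likelihood path in `$ll_trace`.
#' @export
fit_tao_cox <- function(data, covariates = c("w", "x"), x_col = "x",
                        n_bins = 20L, w_levels = NULL, sieve_degree = 2L,
                        max_iter = 500L, tol_beta = 1e-6, tol_ll = 1e-8,
                        se = TRUE, se_step = 0.05, se_coefs = x_col,
                        accelerate = TRUE) {
  if (!all(c("time", "event") %in% names(data)))
    stop("data must contain time and event columns")
  if (sum(data$event) < 1) stop("estimation error: no events")
  prep <- tao_prepare(data, covariates, x_col, n_bins, w_levels,
                      sieve_degree)
  n1 <- prep$n1; n0 <- prep$n0; m <- prep$m; pw <- prep$pw
  cn <- c(prep$wcovs, x_col)

  # support-expanded rows: phase-2 subjects once (observed x), phase-1-only
  # subjects replicated over the support
  W1 <- prep$W[prep$i1, , drop = FALSE]
  W0 <- prep$W[prep$i0, , drop = FALSE]
  Ze <- rbind(cbind(W1, prep$xobs),
              cbind(W0[rep(seq_len(n0), each = m), , drop = FALSE],
                    rep(prep$support, times = n0)))
  colnames(Ze) <- cn
  te <- c(data$time[prep$i1], rep(data$time[prep$i0], each = m))
  de <- c(data$event[prep$i1], rep(data$event[prep$i0], each = m))
  ws <- cox_workspace(te, de)
  subj_grp <- match(data$time, ws$utime)
  d1 <- data$event[prep$i1]; d0 <- data$event[prep$i0]
  e1 <- d1 == 1
  e0 <- d0 == 1
  logp1_idx <- cbind(prep$i1, prep$bins)
  supmat <- if (n0) matrix(prep$support, n0, m, byrow = TRUE) else
    matrix(0, 0, m)

  engine <- function(fix_idx, fix_val, init, iter_cap) {
    free <- setdiff(seq_along(cn), fix_idx)
    Zuse <- if (length(free)) Ze[, free, drop = FALSE] else NULL
    offs <- if (length(fix_idx)) Ze[, fix_idx] * fix_val else NULL
    one_iter <- function(q, state) {
      Cfull <- matrix(0, prep$n, m)
      Cfull[prep$i1, ] <- prep$C1
      if (n0) Cfull[prep$i0, ] <- q
      par <- tao_pxw_mstep(prep, Cfull, state$par)
      logP <- tao_logP(prep, par)
      wts <- if (n0) c(rep(1, n1), as.vector(t(q))) else rep(1, n1)
      nr <- cox_nr(Zuse, wts, ws, offset = offs, beta = state$beta[free])
      beta <- state$beta
      beta[free] <- nr$beta
      if (length(fix_idx)) beta[fix_idx] <- fix_val
      bw <- beta[seq_len(pw)]
      bx <- beta[pw + 1L]
      cum_all <- nr$cumhaz[subj_grp]
      jump_all <- nr$jump[subj_grp]
      eta1 <- (if (pw) drop(W1 %*% bw) else 0) + bx * prep$xobs
      ll1 <- sum(d1 * eta1 - cum_all[prep$i1] * exp(eta1) +
                   logP[logp1_idx]) + sum(log(jump_all[prep$i1][e1]))
      if (n0) {
        eta0 <- (if (pw) matrix(drop(W0 %*% bw), n0, m) else
                   matrix(0, n0, m)) + bx * supmat
        lp <- logP[prep$i0, , drop = FALSE] + d0 * eta0 -
          cum_all[prep$i0] * exp(eta0)
        rmax <- row_max(lp)
        A <- exp(lp - rmax)
        rs <- rowSums(A)
        ll0 <- sum(log(jump_all[prep$i0][e0])) + sum(rmax + log(rs))
        qn <- A / rs
      } else {
        ll0 <- 0
        qn <- q
      }
      list(beta = beta, ll = ll1 + ll0, q = qn, par = par, nr = nr)
    }
    tao_em_drive(one_iter, init, n0, iter_cap, tol_beta, tol_ll, accelerate)
  }

  # warm start from the complete-case fit
  beta0 <- stats::setNames(numeric(pw + 1L), cn)
  cc <- tryCatch({
    ws1 <- cox_workspace(data$time[prep$i1], d1)
    cox_nr(cbind(W1, prep$xobs), rep(1, n1), ws1)
  }, error = function(e) NULL)
  if (!is.null(cc) && all(is.finite(cc$beta))) beta0[] <- cc$beta
  par0 <- tao_pxw_init(prep)
  q0 <- if (n0) {
    pr <- exp(tao_logP(prep, par0)[prep$i0, , drop = FALSE])
    pr / rowSums(pr)
  } else matrix(0, 0, m)
  res <- engine(integer(0), NULL,
                list(beta = beta0, q = q0, par = par0), max_iter)

  sev <- stats::setNames(rep(NA_real_, length(cn)), cn)
  varfail <- FALSE
  if (se) {
    for (nmc in intersect(se_coefs, cn)) {
      j <- match(nmc, cn)
      prof <- function(v) engine(j, v, list(beta = res$beta, q = res$q,
                                            par = res$par), max_iter)$ll
      s <- profile_se(prof, at = res$beta[j], step = se_step,
                      value_at = res$ll)
      if (is.na(s)) varfail <- TRUE
      sev[nmc] <- as.numeric(s)
    }
  }
  cov <- diag(sev^2, nrow = length(sev))
  dimnames(cov) <- list(cn, cn)
  nuis <- list(support = prep$support,
               p_xw = tao_pxw_report(prep, res$par),
               par = res$par,
               baseline = data.frame(time = rev(res$nr$utime),
                                     jump = rev(res$nr$jump),
                                     cumhaz = rev(res$nr$cumhaz)))
  new_twophase_fit("TaoCox", res$beta, sev, cov, loglik = res$ll,
                   converged = res$converged, n_iter = res$iter,
                   n_used = prep$n, nuisance = nuis,
                   ll_trace = res$ll_trace, variance_failure = varfail)
}

#' Semiparametric maximum-likelihood logistic fit for two-phase data
#'
#' Same missing-covariate EM as [fit_tao_cox()], with the Cox outcome density
#' replaced by the Bernoulli likelihood
#' \eqn{\mathrm{expit}(\alpha + \beta_x x + \beta_w'W)^\delta
#'      (1-\mathrm{expit}(\cdot))^{1-\delta}} of the event indicator (the
#' follow-up time is ignored). Coefficients are log odds ratios; the M-step is
#' a weighted logistic fit on the support-expanded data.
#'
#' @inheritParams fit_tao_cox
#' @return A `twophase_fit` labelled `"TaoLG"` (coefficients include the
#'   intercept).
#' @export
fit_tao_logistic <- function(data, covariates = c("w", "x"), x_col = "x",
                             n_bins = 20L, w_levels = NULL, sieve_degree = 2L,
                             max_iter = 500L, tol_beta = 1e-6, tol_ll = 1e-8,
                             se = TRUE, se_step = 0.05, se_coefs = x_col,
                             accelerate = TRUE) {
  if (!"event" %in% names(data)) stop("data must contain an event column")
  if (length(unique(data$event)) < 2)
    stop("estimation error: both outcome classes must be present")
  prep <- tao_prepare(data, covariates, x_col, n_bins, w_levels,
                      sieve_degree)
  n1 <- prep$n1; n0 <- prep$n0; m <- prep$m; pw <- prep$pw
  cn <- c("(Intercept)", prep$wcovs, x_col)
  W1 <- prep$W[prep$i1, , drop = FALSE]
  W0 <- prep$W[prep$i0, , drop = FALSE]
  Xe <- cbind(1, rbind(cbind(W1, prep$xobs),
                       cbind(W0[rep(seq_len(n0), each = m), , drop = FALSE],
                             rep(prep$support, times = n0))))
  colnames(Xe) <- cn
  ye <- c(data$event[prep$i1], rep(data$event[prep$i0], each = m))
  d1 <- data$event[prep$i1]; d0 <- data$event[prep$i0]
  logp1_idx <- cbind(prep$i1, prep$bins)
  supmat <- if (n0) matrix(prep$support, n0, m, byrow = TRUE) else
    matrix(0, 0, m)

  engine <- function(fix_idx, fix_val, init, iter_cap) {
    free <- setdiff(seq_along(cn), fix_idx)
    Xuse <- Xe[, free, drop = FALSE]
    offs <- if (length(fix_idx)) Xe[, fix_idx] * fix_val else NULL
    one_iter <- function(q, state) {
      Cfull <- matrix(0, prep$n, m)
      Cfull[prep$i1, ] <- prep$C1
      if (n0) Cfull[prep$i0, ] <- q
      par <- tao_pxw_mstep(prep, Cfull, state$par)
      logP <- tao_logP(prep, par)
      wts <- if (n0) c(rep(1, n1), as.vector(t(q))) else rep(1, n1)
      ir <- logit_irls(Xuse, ye, wts, offset = offs, beta = state$beta[free])
      beta <- state$beta
      beta[free] <- ir$beta
      if (length(fix_idx)) beta[fix_idx] <- fix_val
      a <- beta[1L]
      bw <- beta[1L + seq_len(pw)]
      bx <- beta[length(cn)]
      eta1 <- a + (if (pw) drop(W1 %*% bw) else 0) + bx * prep$xobs
      ll1 <- sum(d1 * eta1 - log1pexp(eta1) + logP[logp1_idx])
      if (n0) {
        eta0 <- a + (if (pw) matrix(drop(W0 %*% bw), n0, m) else
                       matrix(0, n0, m)) + bx * supmat
        lp <- logP[prep$i0, , drop = FALSE] + d0 * eta0 - log1pexp(eta0)
        rmax <- row_max(lp)
        A <- exp(lp - rmax)
        rs <- rowSums(A)
        ll0 <- sum(rmax + log(rs))
        qn <- A / rs
      } else {
        ll0 <- 0
        qn <- q
      }
      list(beta = beta, ll = ll1 + ll0, q = qn, par = par)
    }
    tao_em_drive(one_iter, init, n0, iter_cap, tol_beta, tol_ll, accelerate)
  }

  beta0 <- stats::setNames(numeric(length(cn)), cn)
  cc <- tryCatch(logit_irls(cbind(1, W1, prep$xobs), d1, rep(1, n1)),
                 error = function(e) NULL)
  if (!is.null(cc) && all(is.finite(cc$beta))) beta0[] <- cc$beta
  par0 <- tao_pxw_init(prep)
  q0 <- if (n0) {
    pr <- exp(tao_logP(prep, par0)[prep$i0, , drop = FALSE])
    pr / rowSums(pr)
  } else matrix(0, 0, m)
  res <- engine(integer(0), NULL,
                list(beta = beta0, q = q0, par = par0), max_iter)

  sev <- stats::setNames(rep(NA_real_, length(cn)), cn)
  varfail <- FALSE
  if (se) {
    for (nmc in intersect(se_coefs, cn)) {
      j <- match(nmc, cn)
      prof <- function(v) engine(j, v, list(beta = res$beta, q = res$q,
                                            par = res$par), max_iter)$ll
      s <- profile_se(prof, at = res$beta[j], step = se_step,
                      value_at = res$ll)
      if (is.na(s)) varfail <- TRUE
      sev[nmc] <- as.numeric(s)
    }
  }
  cov <- diag(sev^2, nrow = length(sev))
  dimnames(cov) <- list(cn, cn)
  nuis <- list(support = prep$support,
               p_xw = tao_pxw_report(prep, res$par),
               par = res$par)
  new_twophase_fit("TaoLG", res$beta, sev, cov, loglik = res$ll,
                   converged = res$converged, n_iter = res$iter,
                   n_used = prep$n, nuisance = nuis,
                   ll_trace = res$ll_trace, variance_failure = varfail)
}

#' Profile-likelihood standard error by numerical curvature
#'
#' \eqn{se = (-d^2\ell_{profile}/d\beta^2)^{-1/2}} estimated by a central
#' second difference at the maximizer. If the curvature estimate is
#' non-negative (profile too flat at the given step), the step is doubled up
#' to `max_expand` times; persistent failure returns `NA` with attribute
#' `failure`.
#'
#' @param objective Function returning the profile log-likelihood of a scalar
#'   coefficient (all other parameters maximized out).
#' @param at The maximizing value of the coefficient.
#' @param step Central-difference step.
#' @param value_at Optional precomputed `objective(at)`.
#' @param max_expand Maximum number of step doublings.
#' @return The standard error (attributes `curvature` and `step`), or `NA`.
#' @examples
#' profile_se(function(b) -(b - 1)^2 / (2 * 0.25), at = 1)  # exactly 0.5
#' @export
profile_se <- function(objective, at, step = 0.05, value_at = NULL,
                       max_expand = 4L) {
  f0 <- value_at %||% objective(at)
  h <- step
  for (k in 0:max_expand) {
    fp <- objective(at + h)
    fm <- objective(at - h)
    curv <- (fp - 2 * f0 + fm) / h^2
    if (is.finite(curv) && curv < 0)
      return(structure(sqrt(-1 / curv), curvature = curv, step = h))
    h <- 2 * h
  }
  structure(NA_real_, failure = TRUE)
}
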