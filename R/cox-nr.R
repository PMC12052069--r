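# Internal weighted Cox partial-likelihood maximizer with Breslow baseline.
#
# Used as the M-step engine of the semiparametric EM, where the same expanded
# design matrix is refit hundreds of times with changing posterior weights:
# the sort order and tie structure are precomputed once (cox_workspace) and
# each Newton-Raphson iteration is a handful of cumulative sums. Rows are
# sorted by DESCENDING time so every risk-set aggregate is a prefix sum.
# Cross-checked against survival::coxph in the test suite.

cox_workspace <- function(time, status) {
  ord <- order(time, decreasing = TRUE)
  ts <- time[ord]
  ds <- status[ord]
  ut <- unique(ts)                  # descending distinct times
  grp <- match(ts, ut)
  n <- length(ts)
  glast <- c(which(grp[-1] != grp[-n]), n)  # last sorted row of each group
  ev <- which(ds > 0)
  list(ord = ord, ds = ds, grp = grp, glast = glast, ev = ev, ge = grp[ev],
       utime = ut, G = length(ut), n = n)
}

# Z, weights, offset in original row order; ws from cox_workspace on the same
# rows. Breslow ties. Returns beta, the weighted partial log-likelihood, and
# the Breslow baseline jumps / cumulative hazard per distinct time (aligned
# with ws$utime, i.e. descending time order).
cox_nr <- function(Z, weights, ws, offset = NULL, beta = NULL,
                   tol = 1e-9, max_iter = 40L) {
  p <- if (is.null(Z)) 0L else ncol(Z)
  Zs <- if (p) Z[ws$ord, , drop = FALSE] else NULL
  wsrt <- weights[ws$ord]
  offs <- if (is.null(offset)) numeric(ws$n) else offset[ws$ord]
  ds <- ws$ds; ev <- ws$ev; ge <- ws$ge; glast <- ws$glast
  wd <- (wsrt * ds)[ev]
  Zev <- if (p) Zs[ev, , drop = FALSE] else NULL
  if (is.null(beta)) beta <- numeric(p)

  ll_of <- function(eta) {
    S0 <- cumsum(wsrt * exp(eta))[glast]
    sum(wd * (eta[ev] - log(S0[ge])))
  }

  eta <- (if (p) drop(Zs %*% beta) else 0) + offs
  ll <- ll_of(eta)
  iter <- 0L
  converged <- p == 0L
  info <- NULL
  while (p > 0L && iter < max_iter) {
    iter <- iter + 1L
    r <- wsrt * exp(eta)
    S0 <- cumsum(r)[glast]
    S1 <- matrix(0, ws$G, p)
    for (a in seq_len(p)) S1[, a] <- cumsum(r * Zs[, a])[glast]
    bar <- S1 / S0
    U <- colSums(wd * (Zev - bar[ge, , drop = FALSE]))
    info <- matrix(0, p, p)
    for (a in seq_len(p)) {
      for (b in a:p) {
        S2ab <- cumsum(r * Zs[, a] * Zs[, b])[glast]
        vab <- S2ab / S0 - bar[, a] * bar[, b]
        info[a, b] <- info[b, a] <- sum(wd * vab[ge])
      }
    }
    step <- tryCatch(solve(info, U), error = function(e)
      stop("estimation error: singular information in Cox update"))
    new_beta <- beta + step
    new_eta <- drop(Zs %*% new_beta) + offs
    new_ll <- ll_of(new_eta)
    halvings <- 0L
    while ((!is.finite(new_ll) || new_ll < ll - 1e-12) && halvings < 30L) {
      step <- step / 2
      halvings <- halvings + 1L
      new_beta <- beta + step
      new_eta <- drop(Zs %*% new_beta) + offs
      new_ll <- ll_of(new_eta)
    }
    dbeta <- max(abs(new_beta - beta))
    dll <- abs(new_ll - ll)
    beta <- new_beta
    eta <- new_eta
    ll <- new_ll
    if (dbeta < tol || dll < 1e-13 * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
  }
  # Breslow baseline at the final estimates
  S0 <- cumsum(wsrt * exp(eta))[glast]
  dwg <- numeric(ws$G)
  agg <- rowsum((wsrt * ds)[ev], ws$ge)        # only event rows contribute
  dwg[as.integer(rownames(agg))] <- agg[, 1]
  jump <- dwg / S0
  # utime is descending, so the cumulative hazard accumulates from the end
  cumhaz <- rev(cumsum(rev(jump)))
  list(beta = beta, loglik = ll, iter = iter, converged = converged,
       info = info, utime = ws$utime, jump = jump, cumhaz = cumhaz)
}

# Weighted logistic IRLS with optional offset and warm start; used as the
# M-step of the logistic-outcome EM (fractional posterior weights).
logit_irls <- function(X, y, w, offset = NULL, beta = NULL,
                       tol = 1e-9, max_iter = 50L) {
  p <- ncol(X)
  offs <- offset %||% numeric(nrow(X))
  if (is.null(beta)) beta <- numeric(p)
  ll_of <- function(eta) sum(w * (y * eta - log1pexp(eta)))
  eta <- drop(X %*% beta) + offs
  ll <- ll_of(eta)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- stats::plogis(eta)
    U <- drop(crossprod(X, w * (y - mu)))
    v <- w * mu * (1 - mu)
    H <- crossprod(X, X * v)
    step <- tryCatch(solve(H, U), error = function(e)
      stop("estimation error: singular information in logistic update"))
    new_beta <- beta + step
    new_eta <- drop(X %*% new_beta) + offs
    new_ll <- ll_of(new_eta)
    halvings <- 0L
    while ((!is.finite(new_ll) || new_ll < ll - 1e-12) && halvings < 30L) {
      step <- step / 2
      halvings <- halvings + 1L
      new_beta <- beta + step
      new_eta <- drop(X %*% new_beta) + offs
      new_ll <- ll_of(new_eta)
    }
    dbeta <- max(abs(new_beta - beta))
    dll <- abs(new_ll - ll)
    beta <- new_beta
    eta <- new_eta
    ll <- new_ll
    if (dbeta < tol || dll < 1e-13 * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, loglik = ll, iter = iter, converged = converged)
}

# row maxima of a matrix without apply(); ties.method = "first" keeps the
# RNG stream untouched
row_max <- function(M) {
  M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
}
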