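#' @title Phase-2 selection objects
#' @description Every sampler returns a `phase2_selection`: a logical inclusion
#'   vector over the cohort, Horvitz-Thompson design weights for the selected
#'   subjects (1/sampling fraction, stratum-specific where applicable), the
#'   design label, and the realized (cases, controls) counts per stratum.
#' @param selected Logical vector over cohort rows.
#' @param weight Numeric weights (set to `NA` for unselected subjects).
#' @param design_label Provenance string, e.g. `"CCH"`.
#' @param n_per_stratum Integer matrix, strata x (cases, controls).
#' @return An object of class `phase2_selection`.
#' @keywords internal
new_selection <- function(selected, weight, design_label, n_per_stratum) {
  weight[!selected] <- NA_real_
  if (any(weight[selected] < 1 - 1e-8, na.rm = TRUE))
    stop("design error: weights must be >= 1")
  structure(list(selected = selected, weight = weight,
                 design_label = design_label, n_per_stratum = n_per_stratum),
            class = "phase2_selection")
}

#' @export
print.phase2_selection <- function(x, ...) {
  cat(sprintf("%s selection: %d subjects in phase 2\n",
              x$design_label, sum(x$selected)))
  print(x$n_per_stratum)
  invisible(x)
}

count_per_stratum <- function(cohort, selected) {
  strata <- sort(unique(cohort$stratum))
  out <- t(vapply(strata, function(k) {
    c(cases = sum(selected & cohort$stratum == k & cohort$event == 1),
      controls = sum(selected & cohort$stratum == k & cohort$event == 0))
  }, c(cases = 0, controls = 0)))
  rownames(out) <- paste0("stratum_", strata)
  out
}

# Split `total` draws across strata with availability caps.
# balanced: as equal as possible; proportional: largest-remainder by availability.
allocate_counts <- function(total, avail, allocation = c("proportional", "balanced")) {
  allocation <- match.arg(allocation)
  S <- length(avail)
  if (total > sum(avail))
    stop("design error: requested sample exceeds available subjects")
  target <- switch(allocation,
                   balanced = rep(total / S, S),
                   proportional = total * avail / sum(avail))
  n <- pmin(floor(target), avail)
  while (sum(n) < total) {
    frac <- target - n
    frac[n >= avail] <- -Inf
    i <- which.max(frac)
    n[i] <- n[i] + 1
  }
  as.integer(n)
}

#' Case-cohort (CCH) phase-2 sampling
#'
#' Cases (`event == 1`) and controls (`event == 0`) are sampled independently;
#' `p = 1` reproduces the classic case-cohort study where every case enters
#' phase 2. With `fixed_count = TRUE` (the default, used to hit an exact
#' budget) exactly `n_cases`/`n_controls` subjects (or `round(p * #cases)`,
#' etc.) are drawn without replacement and weights are the exact inverse
#' sampling fractions; otherwise subjects are included by independent
#' Bernoulli draws with probabilities `p` and `pi` and weights `1/p`, `1/pi`.
#'
#' @param cohort A cohort `data.frame` with columns `time`, `event`, `stratum`.
#' @param p,pi Case/control sampling proportions in (0, 1].
#' @param n_cases,n_controls Alternative fixed-count specification.
#' @param fixed_count Sample exact counts without replacement?
#' @param seed Optional RNG seed (sampling is deterministic given
#'   cohort, specification and seed).
#' @return A `phase2_selection`.
#' @export
sample_cch <- function(cohort, p = NULL, pi = NULL, n_cases = NULL,
                       n_controls = NULL, fixed_count = TRUE, seed = NULL) {
  cases <- which(cohort$event == 1)
  controls <- which(cohort$event == 0)
  if (!length(cases) || !length(controls))
    stop("design error: need at least one case and one control")
  n <- nrow(cohort)
  selected <- logical(n)
  weight <- rep(NA_real_, n)
  with_seed(seed, {
    if (fixed_count) {
      nc <- as.integer(n_cases %||% round((p %||% 1) * length(cases)))
      nk <- as.integer(n_controls %||% round((pi %||% 1) * length(controls)))
      if (nc < 1 || nc > length(cases) || nk < 1 || nk > length(controls))
        stop("design error: sample counts outside the available pools")
      sc <- resample(cases, nc)
      sk <- resample(controls, nk)
      selected[c(sc, sk)] <- TRUE
      weight[sc] <- length(cases) / nc
      weight[sk] <- length(controls) / nk
    } else {
      if (is.null(p) || is.null(pi)) stop("design error: supply p and pi")
      sc <- cases[stats::runif(length(cases)) <= p]
      sk <- controls[stats::runif(length(controls)) <= pi]
      selected[c(sc, sk)] <- TRUE
      weight[sc] <- 1 / p
      weight[sk] <- 1 / pi
    }
  })
  new_selection(selected, weight, "CCH", count_per_stratum(cohort, selected))
}

# shared stratified sampler: `eligible_controls` restricts the control pool
stratified_sample <- function(cohort, eligible_controls, p_by_stratum,
                              pi_by_stratum, n_cases, n_controls, allocation,
                              fixed_count, seed, label) {
  strata <- sort(unique(cohort$stratum))
  S <- length(strata)
  case_pool <- lapply(strata, function(k)
    which(cohort$event == 1 & cohort$stratum == k))
  ctrl_pool <- lapply(strata, function(k)
    which(cohort$event == 0 & cohort$stratum == k & eligible_controls))
  if (any(vapply(case_pool, length, 0L) == 0))
    stop("design error: stratum without cases")
  empty_ctrl <- which(vapply(ctrl_pool, length, 0L) == 0)
  n <- nrow(cohort)
  selected <- logical(n)
  weight <- rep(NA_real_, n)
  with_seed(seed, {
    if (fixed_count) {
      ac <- vapply(case_pool, length, 0L)
      ak <- vapply(ctrl_pool, length, 0L)
      ncs <- if (!is.null(n_cases)) allocate_counts(n_cases, ac, allocation)
        else as.integer(round(rep_len(p_by_stratum %||% 1, S) * ac))
      nks <- if (!is.null(n_controls)) allocate_counts(n_controls, ak, allocation)
        else as.integer(round(rep_len(pi_by_stratum %||% 1, S) * ak))
      if (length(empty_ctrl) && any(nks[empty_ctrl] > 0))
        stop(sprintf("design error: no eligible controls in stratum %s",
                     paste(strata[empty_ctrl], collapse = ", ")))
      if (any(ncs > ac) || any(nks > ak) || any(ncs < 0) || any(nks < 0))
        stop("design error: per-stratum counts outside the available pools")
      for (k in seq_len(S)) {
        if (ncs[k] > 0) {
          s <- resample(case_pool[[k]], ncs[k])
          selected[s] <- TRUE
          weight[s] <- ac[k] / ncs[k]
        }
        if (nks[k] > 0) {
          s <- resample(ctrl_pool[[k]], nks[k])
          selected[s] <- TRUE
          weight[s] <- ak[k] / nks[k]
        }
      }
    } else {
      pb <- rep_len(p_by_stratum %||% 1, S)
      qb <- rep_len(pi_by_stratum %||% 1, S)
      if (length(empty_ctrl) && any(qb[empty_ctrl] > 0))
        stop(sprintf("design error: no eligible controls in stratum %s",
                     paste(strata[empty_ctrl], collapse = ", ")))
      for (k in seq_len(S)) {
        sc <- case_pool[[k]][stats::runif(length(case_pool[[k]])) <= pb[k]]
        sk <- ctrl_pool[[k]][stats::runif(length(ctrl_pool[[k]])) <= qb[k]]
        selected[c(sc, sk)] <- TRUE
        weight[sc] <- 1 / pb[k]
        weight[sk] <- 1 / qb[k]
      }
    }
  })
  new_selection(selected, weight, label, count_per_stratum(cohort, selected))
}

#' Stratified case-cohort (SCCH) sampling
#'
#' Within-stratum case-cohort sampling with stratum-specific weights
#' \eqn{1/p_i} (cases) and \eqn{1/\pi_i} (controls). Strata are taken from the
#' cohort's `stratum` column. Totals (`n_cases`, `n_controls`) are split
#' across strata by the `allocation` rule, capped by availability.
#'
#' @inheritParams sample_cch
#' @param p_by_stratum,pi_by_stratum Per-stratum sampling proportions
#'   (recycled across strata).
#' @param allocation How fixed totals are split across strata:
#'   `"proportional"` (largest-remainder by stratum pool size, the default --
#'   it keeps every stratum-specific weight moderate) or `"balanced"`
#'   (as equal as possible).
#' @return A `phase2_selection`.
#' @export
sample_scch <- function(cohort, p_by_stratum = NULL, pi_by_stratum = NULL,
                        n_cases = NULL, n_controls = NULL,
                        allocation = c("proportional", "balanced"),
                        fixed_count = TRUE, seed = NULL) {
  stratified_sample(cohort, rep(TRUE, nrow(cohort)), p_by_stratum,
                    pi_by_stratum, n_cases, n_controls, match.arg(allocation),
                    fixed_count, seed, "SCCH")
}

#' Stratified extreme case-control (SECC) sampling
#'
#' As [sample_scch()], but the control pool in every stratum is restricted to
#' controls whose follow-up time exceeds the threshold `tau` (extreme,
#' long-followed controls). Cases are sampled as in SCCH. Control weights are
#' inverse sampling fractions of the *eligible* pool.
#'
#' @inheritParams sample_scch
#' @param tau Control follow-up threshold; defaults to the median follow-up
#'   time of the cohort's controls.
#' @return A `phase2_selection`; every selected control has `time > tau`.
#' @export
sample_secc <- function(cohort, p_by_stratum = NULL, pi_by_stratum = NULL,
                        n_cases = NULL, n_controls = NULL, tau = NULL,
                        allocation = c("proportional", "balanced"),
                        fixed_count = TRUE, seed = NULL) {
  tau <- tau %||% stats::median(cohort$time[cohort$event == 0])
  if (tau < 0) stop("design error: tau must be >= 0")
  sel <- stratified_sample(cohort, cohort$time > tau, p_by_stratum,
                           pi_by_stratum, n_cases, n_controls,
                           match.arg(allocation), fixed_count, seed, "SECC")
  sel$tau <- tau
  sel
}

#' Martingale residuals from a phase-1 Cox model
#'
#' Fits a Cox proportional-hazards model of `(time, event)` on the phase-1
#' (inexpensive) covariates only and returns the martingale residuals
#' \eqn{m_i = \delta_i - \hat\Lambda_0(t_i)\, e^{W_i'\hat\eta}} with the
#' Breslow baseline. Residuals lie in \eqn{(-\infty, 1]} and sum to zero at
#' the fitted values.
#'
#' @param cohort A cohort `data.frame`.
#' @param covariates Phase-1 covariate column names (default `"w"`).
#' @return Numeric residual per subject.
#' @export
martingale_residuals <- function(cohort, covariates = "w") {
  if (sum(cohort$event) < 1) stop("estimation error: no events in cohort")
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(covariates, collapse = " + ")))
  bad <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(f, data = cohort, ties = "breslow",
                    control = survival::coxph.control(timefix = FALSE)),
    warning = function(w) {
      if (grepl("converge|infinite|out of iterations", conditionMessage(w))) {
        bad <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (bad) stop("estimation error: phase-1 Cox fit did not converge")
  unname(stats::residuals(fit, type = "martingale"))
}

# enumerate stratum allocations (n_1..n_S) with sum = total, n_i a multiple of
# `step`, n_i <= caps[i]; rows ordered so that earlier strata get larger
# allocations first (ties in the objective then resolve toward low strata).
enumerate_allocations <- function(total, caps, step = 1L) {
  S <- length(caps)
  rec <- function(k, rem) {
    if (k == S) {
      if (rem <= caps[k] && rem %% step == 0) return(matrix(rem, 1, 1))
      return(NULL)
    }
    hi <- min(caps[k], rem)
    hi <- hi - (hi %% step)
    out <- list()
    rest <- sum(caps[(k + 1):S])
    for (nk in seq(hi, 0, by = -step)) {
      if (rem - nk > rest) next
      sub <- rec(k + 1, rem - nk)
      if (!is.null(sub)) out[[length(out) + 1]] <- cbind(nk, sub)
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  res <- rec(1, total)
  if (is.null(res)) matrix(integer(0), 0, S) else unname(res)
}

#' Optimal extreme-martingale-residual (Opt) sampling
#'
#' Phase-2 design driven by martingale residuals of a phase-1 Cox model: for
#' each candidate allocation \eqn{(n_1, \ldots, n_S)} on a grid with
#' \eqn{\sum_i 2 n_i} equal to the budget, stratum \eqn{i} contributes its
#' \eqn{n_i} cases with the largest residuals and its \eqn{n_i} controls with
#' the smallest (most negative) residuals. The grid search retains the
#' allocation maximizing the design objective \eqn{\sum_{selected} m_i^2}
#' (ties resolve toward lower-index strata). Selection is deterministic given
#' the cohort and residuals; weights are 1 because the design is analyzed with
#' likelihood methods, not inverse-probability weighting.
#'
#' @param cohort A cohort `data.frame`.
#' @param budget Total phase-2 size (even; half cases, half controls).
#' @param grid_step Allocation grid resolution (must divide `budget / 2`).
#' @param residuals Optional precomputed martingale residuals
#'   (see [martingale_residuals()]).
#' @param covariates Phase-1 covariates for the residual model.
#' @param allocations Optional integer matrix of candidate allocations
#'   (rows = allocations, columns = strata), overriding the grid.
#' @param seed Unused (the design is deterministic); accepted for interface
#'   uniformity with the other samplers.
#' @return A `phase2_selection` with the chosen allocation in
#'   `n_per_stratum` and the objective value in `objective`.
#' @export
sample_opt <- function(cohort, budget, grid_step = 1L, residuals = NULL,
                       covariates = "w", allocations = NULL, seed = NULL) {
  n <- nrow(cohort)
  if (budget %% 2 != 0 || budget < 2 || budget > n)
    stop("design error: budget must be even, >= 2 and <= cohort size")
  pairs <- budget %/% 2
  m <- residuals %||% martingale_residuals(cohort, covariates)
  strata <- sort(unique(cohort$stratum))
  S <- length(strata)
  case_ord <- vector("list", S)
  ctrl_ord <- vector("list", S)
  cum_case <- vector("list", S)
  cum_ctrl <- vector("list", S)
  caps <- integer(S)
  for (k in seq_len(S)) {
    ci <- which(cohort$event == 1 & cohort$stratum == strata[k])
    oi <- which(cohort$event == 0 & cohort$stratum == strata[k])
    ci <- ci[order(m[ci], decreasing = TRUE)]   # largest residuals first
    oi <- oi[order(m[oi])]                      # most negative first
    case_ord[[k]] <- ci
    ctrl_ord[[k]] <- oi
    cum_case[[k]] <- c(0, cumsum(m[ci]^2))
    cum_ctrl[[k]] <- c(0, cumsum(m[oi]^2))
    caps[k] <- min(length(ci), length(oi))
  }
  if (is.null(allocations)) {
    if (pairs %% grid_step != 0)
      stop("design error: grid_step must divide budget/2")
    allocations <- enumerate_allocations(pairs, caps, as.integer(grid_step))
  } else {
    allocations <- as.matrix(allocations)
    keep <- rowSums(allocations) == pairs & !apply(allocations, 1,
                                                  function(a) any(a > caps | a < 0))
    allocations <- allocations[keep, , drop = FALSE]
  }
  if (nrow(allocations) == 0)
    stop("design error: budget exceeds available extremes in every allocation")
  obj <- apply(allocations, 1, function(a)
    sum(vapply(seq_len(S), function(k)
      cum_case[[k]][a[k] + 1] + cum_ctrl[[k]][a[k] + 1], 0)))
  best <- allocations[which.max(obj), ]
  selected <- logical(n)
  for (k in seq_len(S)) {
    if (best[k] > 0) {
      selected[case_ord[[k]][seq_len(best[k])]] <- TRUE
      selected[ctrl_ord[[k]][seq_len(best[k])]] <- TRUE
    }
  }
  nps <- cbind(cases = as.integer(best), controls = as.integer(best))
  rownames(nps) <- paste0("stratum_", strata)
  sel <- new_selection(selected, rep(1, n), "Opt", nps)
  sel$objective <- max(obj)
  sel
}

#' Phase-2 view of a cohort under a selection
#'
#' Returns the cohort with the expensive covariate masked to `NA` for
#' unselected subjects, plus `selected` (the phase-2 indicator R) and
#' `weight` columns. This is the input expected by the semiparametric
#' maximum-likelihood estimators, which use phase-1 rows of every subject.
#'
#' @param cohort A cohort `data.frame`.
#' @param selection A `phase2_selection`.
#' @param x_cols Expensive covariate column(s) to mask (default `"x"`).
#' @return A `data.frame` with the same rows as `cohort`.
#' @export
phase2_data <- function(cohort, selection, x_cols = "x") {
  stopifnot(inherits(selection, "phase2_selection"),
            length(selection$selected) == nrow(cohort))
  df <- as.data.frame(cohort)
  df$selected <- selection$selected
  df$weight <- selection$weight
  for (cc in x_cols) df[[cc]][!selection$selected] <- NA
  attr(df, "design_label") <- selection$design_label
  df
}
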