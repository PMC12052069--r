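---
title: "Two-phase sampling designs and estimators for time-to-event outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase sampling designs and estimators for time-to-event outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twophasesurv)
```

## The problem

Genomic studies of time-to-event outcomes (relapse, survival) often cannot
afford the expensive measurement — a sequencing-derived subtype, say — on the
whole cohort. A *two-phase* study measures cheap variables (follow-up time
$t$, event status $\delta$, inexpensive covariates $W$) on everyone in phase
1, then selects a subset for the expensive covariate $X$ in phase 2. The
choice of phase-2 design and of the analysis method determines the power of
the study and the interpretability of the estimated effect. This package
implements, as reusable and tested components, the designs and estimators
needed to compare those choices by simulation, and to analyze a real
two-phase table with the same code.

## The data-generating model

Cohorts are simulated from a Weibull proportional-hazards model,

$$h(t \mid z) = \gamma \lambda t^{\gamma-1} e^{z'\beta}, \qquad
  S(t \mid z) = \exp\!\big(-\lambda t^{\gamma} e^{z'\beta}\big),$$

with $z = (W, X)$: one inexpensive covariate $W \sim N(0,1)$ and one
expensive covariate $X = \rho W + \sqrt{1-\rho^2}\,\epsilon$ (standard
normal; a binary variant thresholds the latent variable at zero so the
correlated scenario stays well defined). $\beta$ are log hazard ratios;
$\rho = 0$ and $\rho = 0.5$ give the independent and correlated scenarios.
Latent times are drawn by inverse transform,
$T = (-\log U / (\lambda e^{z'\beta}))^{1/\gamma}$.

**Censoring.** Censoring is administrative at a horizon $c$ with uniform
staggered entry: each subject's censoring time is $C \sim U((1-a)c,\, c)$,
with accrual fraction $a = 1$ by default. A fixed common horizon ($a = 0$) is
available, but it makes every control's follow-up identical, which
degenerates both the extreme case-control design (no control exceeds a
threshold strictly) and the residual-based optimal design; staggered entry is
also what the motivating multi-year trials actually look like. This is the
one place where the generator deliberately goes beyond a bare
administrative cutoff.

**Calibration.** Rather than fixing $\lambda$ directly, a target case
proportion can be supplied; `calibrate_scale()` solves
$E[P(T \le C \mid W, X)] = \text{target}$ by root finding on a
Gauss–Legendre quadrature of the event probability (no simulation involved).
The default study conditions mirror the evaluated scenarios: cohorts of
$n = 3{,}000$ with 100 cases and 100 controls in phase 2, shapes
$\gamma \in \{0.1, 0.3, 0.5, 0.7\}$ calibrated to case proportions of about
0.11, 0.155, 0.22 and 0.31 (the midpoints of the reported ranges), moderate
log hazard ratios around $\log 2$, and 2,000-replicate studies scaled down to
500 (fast estimators) with Monte-Carlo standard errors reported so reduced
runs stay interpretable.

## Phase-2 designs

All samplers map a cohort to a `phase2_selection` (inclusion indicator +
design weight + realized per-stratum counts). Strata are quantile bins of
$W$ (two by default; a binary covariate yields its natural categories).

* **CCH** — case-cohort: cases with proportion $p$ ($p = 1$ is the classic
  design), controls with proportion $\pi$; weights $1/p$, $1/\pi$. The
  default fixed-count variant draws exact numbers without replacement so the
  budget of 100 + 100 is hit exactly, with weights the exact inverse
  sampling fractions.
* **SCCH** — the same within strata, weights $1/p_i$, $1/\pi_i$. Fixed
  totals are split across strata by an allocation rule (see below).
* **SECC** — stratified extreme case-control: controls are eligible only if
  their follow-up exceeds a threshold $\tau$ (default: the median control
  follow-up; the threshold is a design knob the literature leaves open).
* **Opt** — the optimal design: martingale residuals
  $m_i = \delta_i - \hat\Lambda_0(t_i)e^{W_i'\hat\eta}$ from a phase-1 Cox
  model rank subjects; for each stratum allocation $(n_1,\dots,n_S)$ on a
  grid with $\sum_i 2n_i$ equal to the budget, stratum $i$ contributes its
  $n_i$ largest-residual cases and $n_i$ most-negative-residual controls,
  and the grid search keeps the allocation maximizing
  $\sum_{\text{selected}} m_i^2$. The published account specifies the
  extreme-residual selection and the grid search but not the variance
  criterion itself, which lives in unpublished supplementary material; the
  $\sum m^2$ objective is this package's concrete stand-in — it is the
  quantity that drives the information contributed by extreme residuals, it
  makes the grid search well defined, and it reduces to balanced extreme
  sampling when only the balanced allocation is feasible. Ties prefer
  lower-index strata; the whole design is deterministic given the cohort.

**Allocation rule.** For fixed stratum totals the package defaults to
*proportional* allocation (largest-remainder split proportional to the
stratum pools, capped by availability), with *balanced* allocation as an
option. Proportional allocation keeps every stratum-specific sampling
fraction moderate; balanced allocation can drive a small stratum to
near-exhaustive sampling (weights near 1 next to weights near 10), which in
simulations at these budgets produced a visible finite-sample bias in the
weighted Cox estimator, while proportional allocation kept it within
Monte-Carlo noise of zero.

## Analysis methods

* **Cox** (full cohort) and **CoxW** (weighted phase-2 subset) go through
  `survival::coxph` with Breslow ties; `CoxW` uses the design weights and the
  robust (Lin–Ying) sandwich variance without finite-population corrections.
  At the common-event setting its confidence intervals are essentially
  nominal (~95%); at the rare-event setting, where control weights approach
  30, the sandwich understates the Monte-Carlo standard deviation by
  roughly 10% and coverage drops to about 0.91 — the known price of the
  uncorrected sandwich in case-cohort samples with few, heavily weighted
  controls.
  `timefix` is disabled so that the continuous simulated times (which span
  many orders of magnitude under small Weibull shapes) are not coarsened
  into artificial ties.
* **LG** — logistic regression of $\delta$ on $(W, X)$ in the phase-2
  sample. Its coefficient is a log odds ratio, not a log hazard ratio; under
  rare events the two approximate each other, and part of the evaluation
  surface is exactly how that approximation degrades.
* **TaoLG / TaoCox** — semiparametric maximum likelihood over *all* phase-1
  subjects plus the phase-2 measurements, treating $X$ as missing where
  unselected, with a conditional distribution $P(X = x_j \mid W)$ over a
  finite support (a quadratic multinomial-logit sieve in $w$ by default, a
  per-level table on request) and (for TaoCox) a nonparametric baseline
  hazard with
  jumps at the event times. Valid whenever selection depends only on phase-1
  observables — which covers every design above, including the
  residual-based optimal design.

### The EM algorithm

For unselected subjects the E-step computes posterior support weights
$q_{ij} \propto P(x_j \mid W_i)\, f(t_i, \delta_i \mid x_j, W_i)$; the M-step
refits $P(X|W)$ against the posterior counts (closed-form frequencies for
the table model, a concave Newton multinomial fit for the sieve) and the
outcome model by a weighted fit on the support-expanded data — a weighted Breslow-baseline
Cox Newton–Raphson written for this package (the same expanded design matrix
is refit hundreds of times with changing weights, so the sort order and risk
sets are precomputed once; the engine is cross-checked against
`survival::coxph` in the tests), or a weighted logistic IRLS. Because both
M-steps fully maximize, the observed-data log-likelihood cannot decrease;
the implementation asserts this at every iteration.

Numerical choices that matter:

* **Support**: continuous $X$ is discretized to `n_bins` equal-frequency
  bins of the observed phase-2 values (bin means as support). The package
  default is 20 bins; the simulation harness uses 8, which at these sample
  sizes (200 observed $X$ values) changes the estimates by far less than
  their Monte-Carlo error (the hazard-ratio recovery checks show relative
  biases of about 0.01 at this support size) while cutting the cost of
  every E/M sweep by more than half.
* **Conditional model**: the default $P(X = x_j \mid W)$ is a
  multinomial-logit sieve $\mathrm{softmax}_j(a_j + b_j w + c_j w^2)$, a
  quadratic polynomial in the (standardized) first phase-1 covariate; a
  per-level conditional table is available by passing explicit `w_levels`,
  and the degree is configurable (`sieve_degree`). The smoothness is *not*
  cosmetic: with a conditional table on coarse levels, designs whose
  selection depends strongly on $W$ *within* a level — the optimal design,
  whose residual ranking varies continuously with $W$ — make the coarsened
  model's missing-at-random factorization fail badly enough to bias the
  null distribution of $\hat\beta_x$ and inflate type I error severalfold
  (with independent covariates the bias disappears, confirming the
  mechanism; refining the table to 10 levels only shrank it). The smooth
  sieve both removes the bias and cures the slow, flat-ridge EM convergence
  that the many-parameter table induces; it plays the role of the B-spline
  sieve in the estimator this implementation follows, of which discrete
  levels are the piecewise-constant special case. The M-step for the sieve
  is a concave Newton fit of a fractional-count multinomial logistic
  regression, fully maximized, so the EM ascent property is untouched.
* **Convergence**: the fitters stop when the largest coefficient change is
  below `tol_beta` ($10^{-6}$ by default) *and* the relative log-likelihood
  change is below $10^{-8}$, capped at 500 sweeps. Under the optimal design
  the nonparametric nuisance sits on a statistically flat ridge and plain EM
  crawls (thousands of sweeps); the driver therefore uses SQUAREM
  extrapolation of the posterior weights with an adaptive step cap,
  accepting an extrapolated point only when the observed log-likelihood does
  not decrease — the monotone EM guarantee is preserved exactly, typically
  at a 3–10 fold reduction in sweeps. The simulation harness additionally
  passes `tol_beta = 1e-4` and a relative log-likelihood tolerance of
  $10^{-7}$: on the flat ridge the extra sweeps to the defaults move the
  estimate by under $10^{-3}$, two orders of magnitude below its
  Monte-Carlo standard error, at several times the cost.
* **Standard errors** are profile-likelihood curvatures: the profile
  log-likelihood of a single coefficient is re-maximized (warm-started EM)
  at $\hat\beta \pm h$ and differentiated by central second difference
  ($h = 0.05$ by default, doubled adaptively if the curvature estimate is
  not negative). A Louis-formula observed-information variance is not
  implemented. In null simulations the profile standard error tracks the
  Monte-Carlo standard deviation to within a few percent for the extreme
  case-control design and for the Cox-model fit under the optimal design;
  for the logistic-model fit under the optimal design — the combination
  with the heaviest estimator tails — it understates the sampling spread by
  roughly 15–20%, so that pair's Wald test runs mildly hot (empirical size
  near 0.08–0.10 at nominal 0.05).

## The evaluation harness

`run_experiment()` reproduces the comparison study: per replicate one cohort
feeds every design (paired comparisons), each design is analyzed by its
legal methods (full cohort–Cox; CCH/SCCH–CoxW; SECC/Opt–LG, TaoLG, TaoCox),
and the table reports rejection rate (type I error under $\beta_x = 0$,
power otherwise) with $\sqrt{r(1-r)/n}$ Monte-Carlo error, mean estimate,
(relative) bias against the true log hazard ratio, RMSE, and RMSE relative
to the CCH/CoxW reference. Replicate seeds derive deterministically from the
master seed and every design draws from its own substream, so adding or
removing designs or methods never perturbs the others' estimates.
Non-convergent fits are excluded and counted (a warning fires beyond 2%).

```{r example, eval = FALSE}
setting <- sim_setting(gamma = 0.5, beta_w = log(2), beta_x = log(1.5),
                       rho = 0.5, target_case_prop = 0.22)
metrics <- run_experiment(setting, n_reps = 500, seed = 1)
power_comparison_report(metrics)
```

## What the generator does and does not emulate

The synthetic cohorts reproduce the structure the comparison needs:
proportional hazards with a Weibull baseline, one cheap and one expensive
covariate with controllable correlation, case proportions spanning rare to
common, exact phase-2 budgets. They do **not** emulate competing risks,
time-varying covariates or effects, non-Weibull baselines, covariate-driven
censoring, ties from coarse time recording, or the multi-covariate
adjustment sets of a real analysis (age, sex, ancestry, trial). Passing
tests on these cohorts therefore demonstrate correctness of the estimators
and the internal consistency of the design comparison — not that any
particular real study will show the same power ordering.

## Known limitations

* The optimal design's objective is the documented $\sum m^2$ surrogate,
  not the unpublished variance criterion; numerical agreement with the
  original authors' software is not claimed (their selection rule — extreme
  martingale residuals with grid-searched allocation — is reproduced
  exactly). The surrogate reproduces the design's large power advantage at
  common event proportions, but at rare events and mid-range effect sizes
  it can select covariate-imbalanced extremes and fall several points below
  the stratified case-cohort design — a variance-aware allocation objective
  would likely close that gap.
* Profile-likelihood standard errors cost two warm-started EM runs per
  coefficient; by default only the expensive covariate gets one.
* Multiple expensive covariates are supported only through joint
  discretization of the support, which grows multiplicatively and is
  expensive — consistent with these estimators targeting a single
  association parameter at a time.
* The weighted Cox variance is the robust sandwich, slightly conservative
  relative to finite-population-corrected variants.
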