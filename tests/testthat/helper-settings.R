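# shared fixtures, built in code

# study-condition settings used across tests (cohort n = 3000,
# 100 cases + 100 controls, correlated covariates)
rare_setting <- function(beta_x = log(2), ...)
  sim_setting(gamma = 0.1, beta_w = log(2), beta_x = beta_x, rho = 0.5,
              target_case_prop = 0.11, ...)

common_setting <- function(beta_x = log(1.5), ...)
  sim_setting(gamma = 0.5, beta_w = log(2), beta_x = beta_x, rho = 0.5,
              target_case_prop = 0.22, ...)

null_setting <- function(...)
  sim_setting(gamma = 0.3, beta_w = log(2), beta_x = 0, rho = 0.5,
              target_case_prop = 0.155, ...)

# a small quick cohort for unit tests
small_cohort <- function(n = 400, seed = 7, beta_x = log(2), gamma = 0.5) {
  budget <- max(5L, n %/% 12)
  s <- sim_setting(gamma = gamma, beta_w = log(2), beta_x = beta_x, rho = 0.5,
                   target_case_prop = 0.3, n_cohort = n,
                   n_case_sample = budget, n_control_sample = budget)
  simulate_cohort(s, seed = seed)
}
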