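# Baseline survival parameters of the bundled two-arm comparison,
# used across test files.
base_params <- list(
  ico_pfs = weibull_params(gamma = 0.9359, log_lambda = -5.0757),
  gef_pfs = weibull_params(gamma = 0.94,   log_lambda = -5.2677),
  ico_os  = weibull_params(gamma = 1.1664, log_lambda = -7.3062),
  gef_os  = weibull_params(gamma = 1.1938, log_lambda = -7.5374)
)

# Exact curve points generated by the closed-form Weibull survival.
exact_curve <- function(params, times) {
  km_curve(times, weibull_survival(params, times))
}

# Brute-force oracle: constant-probability cohort trace via powers of
# the explicit 3x3 transition matrix.
matrix_trace <- function(p_dp, p_death, n) {
  M <- rbind(c(1 - p_dp - p_death, p_dp, p_death),
             c(0, 1 - p_death, p_death),
             c(0, 0, 1))
  occ <- matrix(NA_real_, n + 1L, 3L)
  state <- c(1, 0, 0)
  occ[1L, ] <- state
  for (t in seq_len(n)) {
    state <- as.numeric(state %*% M)
    occ[t + 1L, ] <- state
  }
  occ
}
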