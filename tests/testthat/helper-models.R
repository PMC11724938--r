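# small model builders shared across tests

# univariate AR(1) with a single indicator (p = q = 1, no covariates)
scalar_model <- function(ar = 0.5, q_var = 2, lam = 1, r_var = 1,
                         tau = 0, free = NULL) {
  model_params(
    transition = matrix(ar, 1, 1),
    dyn_intercept = 0,
    dyn_covariate_weights = matrix(0, 1, 0),
    process_noise_cov = matrix(q_var, 1, 1),
    meas_intercept = tau,
    loadings = matrix(lam, 1, 1),
    meas_covariate_weights = matrix(0, 1, 0),
    meas_noise_cov = matrix(r_var, 1, 1),
    free = free
  )
}

# identity-loading bivariate model (p = q = 2), optionally near-noiseless
ident_model <- function(ar = 0.4, r_var = 1) {
  model_params(
    transition = diag(ar, 2),
    dyn_intercept = c(0, 0),
    dyn_covariate_weights = matrix(0, 2, 0),
    process_noise_cov = diag(c(1, 2)),
    meas_intercept = c(1, -1),
    loadings = diag(2),
    meas_covariate_weights = matrix(0, 2, 0),
    meas_noise_cov = diag(r_var, 2)
  )
}

# deterministic tiny masked fixture panel (cached per session)
fixture_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture()
    cache
  }
})
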