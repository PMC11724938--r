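#' Bivariate PFA simulation preset
#'
#' The data-generating model used throughout the package's simulation
#' study: a bivariate VAR(1) latent process with one binary and one
#' continuous time-varying covariate, measured by six indicators (three per
#' factor, anchor loadings fixed at 1). True values: AR coefficients
#' `a1 = a2 = 0.5` (low autocorrelation) or `0.7` (high), cross-regressions
#' `b1 = -0.2`, `b2 = -0.3`, covariate effects `c1 = 0.3`, `c2 = -0.3`,
#' `d1 = 0.5`, `d2 = -0.4`, process noise `var1 = 2`, `cov = 0.5`,
#' `var2 = 6`, intercepts 3, free loadings `lambda1 = lambda3 = 2`,
#' `lambda2 = lambda4 = 1`, and unit measurement error variances.
#'
#' @param autocorr `"low"` (AR = 0.5) or `"high"` (AR = 0.7).
#' @param null_effects set the cross-regression and covariate coefficients
#'   to zero (type-I-error study variant); the free map is unchanged.
#' @param covariates include covariate effects. With `FALSE`, B and A are
#'   fixed at zero and excluded from the free map — the template used to
#'   extract factor scores from incomplete data.
#' @return a `mifs_model` with true values and default free map.
#' @export
pfa_template <- function(autocorr = c("low", "high"), null_effects = FALSE,
                         covariates = TRUE) {
  autocorr <- match.arg(autocorr)
  a <- if (autocorr == "low") 0.5 else 0.7
  b1 <- -0.2; b2 <- -0.3
  c1 <- 0.3; c2 <- -0.3; d1 <- 0.5; d2 <- -0.4
  if (null_effects) b1 <- b2 <- c1 <- c2 <- d1 <- d2 <- 0
  F <- matrix(c(a, b2, b1, a), 2, 2)          # [[a1, b1], [b2, a2]]
  B <- matrix(c(c1, c2, d1, d2), 2, 2)        # [[c1, d1], [c2, d2]]
  if (!covariates) B <- matrix(0, 2, 2)
  Q <- matrix(c(2, 0.5, 0.5, 6), 2, 2)
  Lam <- rbind(c(1, 0), c(2, 0), c(1, 0),
               c(0, 1), c(0, 2), c(0, 1))
  A <- matrix(0, 6, 2)

  fm <- rbind(
    free_map(c("a1", "a2", "b1", "b2"), "transition",
             row = c(1, 2, 1, 2), col = c(1, 2, 2, 1)),
    if (covariates)
      free_map(c("c1", "c2", "d1", "d2"), "dyn_covariate_weights",
               row = c(1, 2, 1, 2), col = c(1, 1, 2, 2)),
    free_map(c("zeta_var1", "zeta_cov", "zeta_var2"), "process_noise_cov",
             row = c(1, 2, 2), col = c(1, 1, 2)),
    free_map(paste0("mu", 1:6), "meas_intercept", row = 1:6),
    free_map(paste0("lambda", 1:4), "loadings",
             row = c(2, 3, 5, 6), col = c(1, 1, 2, 2)),
    free_map(paste0("eps_var", 1:6), "meas_noise_cov", row = 1:6, col = 1:6)
  )

  model_params(
    transition = F,
    dyn_intercept = c(0, 0),
    dyn_covariate_weights = B,
    process_noise_cov = Q,
    meas_intercept = rep(3, 6),
    loadings = Lam,
    meas_covariate_weights = A,
    meas_noise_cov = diag(6),
    free = fm
  )
}

#' True parameter values of a preset as a named vector
#'
#' Convenience lookup used by the Monte Carlo harness: the free parameters
#' of a template evaluated at its stored (true) values.
#'
#' @param template a `mifs_model` whose entries hold the generating values.
#' @return named numeric vector.
#' @export
true_values <- function(template) get_theta(template)
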