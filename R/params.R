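#' Construct the time-invariant parameter set of a linear state-space model
#'
#' Container for all time-invariant parameters of the linear Gaussian
#' state-space model
#' \deqn{\eta_t = \alpha + F \eta_{t-1} + B x_t + \zeta_t, \quad
#'       \zeta_t \sim N(0, \Sigma_\zeta)}
#' \deqn{y_t = \tau + \Lambda \eta_t + A x_t + \epsilon_t, \quad
#'       \epsilon_t \sim N(0, \Sigma_\epsilon)}
#' of which the process factor analysis (PFA) model is a special case.
#'
#' @param transition q x q transition matrix F.
#' @param dyn_intercept length-q intercept vector of the dynamic model.
#' @param dyn_covariate_weights q x r matrix B of covariate effects on the
#'   latent states (use a zero-column matrix when there are no covariates).
#' @param process_noise_cov q x q process noise covariance (symmetric PSD).
#' @param meas_intercept length-p vector of measurement intercepts.
#' @param loadings p x q factor loading matrix; one loading per factor
#'   should be fixed at 1 for identification.
#' @param meas_covariate_weights p x r matrix A of covariate effects on the
#'   indicators.
#' @param meas_noise_cov p x p measurement error covariance; only diagonal
#'   matrices are supported for estimation.
#' @param init_mean,init_cov optional initial state mean/covariance for the
#'   first occasion; when `NULL` the stationary solution implied by the
#'   other parameters is used.
#' @param free free-parameter map as returned by [free_map()]; `NULL` means
#'   all parameters fixed (e.g. a pure simulation template).
#' @return An object of class `mifs_model`.
#' @export
model_params <- function(transition, dyn_intercept, dyn_covariate_weights,
                         process_noise_cov, meas_intercept, loadings,
                         meas_covariate_weights, meas_noise_cov,
                         init_mean = NULL, init_cov = NULL, free = NULL) {
  F <- as.matrix(transition)
  q <- nrow(F)
  stopifnot(ncol(F) == q)
  Lam <- as.matrix(loadings)
  p <- nrow(Lam)
  if (ncol(Lam) != q) stop("loadings must have q = ", q, " columns")
  B <- as.matrix(dyn_covariate_weights)
  A <- as.matrix(meas_covariate_weights)
  r <- ncol(B)
  if (nrow(B) != q) stop("dyn_covariate_weights must have q rows")
  if (nrow(A) != p || ncol(A) != r) {
    stop("meas_covariate_weights must be p x r (", p, " x ", r, ")")
  }
  Q <- as.matrix(process_noise_cov)
  R <- as.matrix(meas_noise_cov)
  if (!isTRUE(all.equal(Q, t(Q)))) stop("process_noise_cov not symmetric")
  if (!isTRUE(all.equal(R, t(R)))) stop("meas_noise_cov not symmetric")
  check_psd(Q, "process_noise_cov")
  check_psd(R, "meas_noise_cov")
  if (length(dyn_intercept) != q) stop("dyn_intercept must have length q")
  if (length(meas_intercept) != p) stop("meas_intercept must have length p")
  if (!is.null(init_cov)) check_psd(as.matrix(init_cov), "init_cov")

  m <- structure(list(
    transition = F,
    dyn_intercept = as.numeric(dyn_intercept),
    dyn_covariate_weights = B,
    process_noise_cov = Q,
    meas_intercept = as.numeric(meas_intercept),
    loadings = Lam,
    meas_covariate_weights = A,
    meas_noise_cov = R,
    init_mean = if (is.null(init_mean)) NULL else as.numeric(init_mean),
    init_cov = if (is.null(init_cov)) NULL else as.matrix(init_cov),
    free = free,
    p = p, q = q, r = r
  ), class = "mifs_model")
  m
}

check_psd <- function(M, what) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(1, abs(ev[1])))) {
    stop(what, " is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  }
  invisible(TRUE)
}

#' Free-parameter map entry
#'
#' Defines which entries of a `mifs_model` are estimated. Each row names one
#' natural-scale parameter, the matrix block it lives in, and its position.
#' Variance-type blocks are transformed internally for unconstrained
#' optimization (log for diagonal error variances, log-Cholesky for the
#' process noise covariance).
#'
#' @param name parameter labels (unique).
#' @param block block names, one of `"transition"`,
#'   `"dyn_covariate_weights"`, `"dyn_intercept"`, `"process_noise_cov"`,
#'   `"meas_intercept"`, `"loadings"`, `"meas_covariate_weights"`,
#'   `"meas_noise_cov"`.
#' @param row,col entry positions within the block (col ignored for
#'   vector-valued blocks).
#' @return data.frame usable as the `free` field of [model_params()].
#' @export
free_map <- function(name, block, row, col = 1L) {
  df <- data.frame(name = as.character(name), block = as.character(block),
                   row = as.integer(row), col = as.integer(col),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$name)) stop("duplicate parameter names in free map")
  bad <- setdiff(df$block, c("transition", "dyn_covariate_weights",
                             "dyn_intercept", "process_noise_cov",
                             "meas_intercept", "loadings",
                             "meas_covariate_weights", "meas_noise_cov"))
  if (length(bad)) stop("unknown block(s): ", paste(bad, collapse = ", "))
  df
}

block_is_vector <- function(block) {
  block %in% c("dyn_intercept", "meas_intercept")
}

#' Extract the free parameters of a model as a named natural-scale vector
#' @param model a `mifs_model`.
#' @return named numeric vector in free-map order.
#' @export
get_theta <- function(model) {
  fm <- model$free
  if (is.null(fm) || nrow(fm) == 0) return(numeric(0))
  th <- numeric(nrow(fm))
  for (k in seq_len(nrow(fm))) {
    bl <- model[[fm$block[k]]]
    th[k] <- if (block_is_vector(fm$block[k])) bl[fm$row[k]] else
      bl[fm$row[k], fm$col[k]]
  }
  stats::setNames(th, fm$name)
}

#' Write a natural-scale free-parameter vector back into a model
#' @param model a `mifs_model`.
#' @param theta numeric vector in free-map order.
#' @return the updated model.
#' @export
set_theta <- function(model, theta) {
  fm <- model$free
  stopifnot(length(theta) == NROW(fm))
  for (k in seq_len(NROW(fm))) {
    b <- fm$block[k]
    if (block_is_vector(b)) {
      model[[b]][fm$row[k]] <- theta[k]
    } else {
      model[[b]][fm$row[k], fm$col[k]] <- theta[k]
      if (b %in% c("process_noise_cov", "meas_noise_cov")) {
        model[[b]][fm$col[k], fm$row[k]] <- theta[k]
      }
    }
  }
  model
}

# --- transforms between natural-scale theta and unconstrained phi -------

# process_noise_cov free entries must cover a full lower triangle of the
# leading principal submatrix they touch; they are jointly reparameterized
# through the log-Cholesky factor. Diagonal meas_noise_cov entries use log.

theta_to_phi <- function(model, theta) {
  fm <- model$free
  phi <- theta
  idx_q <- which(fm$block == "process_noise_cov")
  if (length(idx_q)) {
    m2 <- set_theta(model, theta)
    S <- m2$process_noise_cov
    L <- t(chol(S + diag(1e-12, nrow(S))))
    for (k in idx_q) {
      i <- max(fm$row[k], fm$col[k]); j <- min(fm$row[k], fm$col[k])
      phi[k] <- if (i == j) log(L[i, i]) else L[i, j]
    }
  }
  idx_r <- which(fm$block == "meas_noise_cov")
  phi[idx_r] <- log(pmax(theta[idx_r], 1e-12))
  phi
}

phi_to_theta <- function(model, phi) {
  fm <- model$free
  theta <- phi
  idx_q <- which(fm$block == "process_noise_cov")
  if (length(idx_q)) {
    qd <- model$q
    L <- t(chol(model$process_noise_cov + diag(1e-12, qd)))
    for (k in idx_q) {
      i <- max(fm$row[k], fm$col[k]); j <- min(fm$row[k], fm$col[k])
      L[i, j] <- if (i == j) exp(phi[k]) else phi[k]
    }
    S <- L %*% t(L)
    for (k in idx_q) theta[k] <- S[fm$row[k], fm$col[k]]
  }
  idx_r <- which(fm$block == "meas_noise_cov")
  theta[idx_r] <- exp(phi[idx_r])
  theta
}

#' Test stability of a transition matrix
#'
#' A VAR(1)/state-space transition matrix is stable when all eigenvalues
#' have modulus strictly below one, so that the latent process has a
#' stationary distribution.
#'
#' @param transition square transition matrix.
#' @return `TRUE` iff the maximum eigenvalue modulus is < 1.
#' @export
is_stable <- function(transition) {
  F <- as.matrix(transition)
  stopifnot(nrow(F) == ncol(F))
  max(Mod(eigen(F, only.values = TRUE)$values)) < 1
}

#' Stationary mean and covariance of the latent process
#'
#' Solves the discrete Lyapunov equation
#' \eqn{\Gamma = F \Gamma F' + (B V_x B' + \Sigma_\zeta)} for the stationary
#' covariance and \eqn{\mu = (I-F)^{-1}(\alpha + B \mu_x)} for the
#' stationary mean, treating covariates as i.i.d. noise with the given
#' moments.
#'
#' @param params a `mifs_model`.
#' @param covariate_mean length-r mean of the covariates (default zero).
#' @param covariate_var r x r covariance of the covariates (default zero).
#' @return list with elements `mean` (length q) and `cov` (q x q).
#' @export
stationary_moments <- function(params, covariate_mean = NULL,
                               covariate_var = NULL) {
  F <- params$transition
  q <- params$q
  ev <- eigen(F, only.values = TRUE)$values
  if (max(Mod(ev)) >= 1) {
    stop("transition matrix is unstable: eigenvalue with modulus ",
         format(max(Mod(ev))))
  }
  B <- params$dyn_covariate_weights
  r <- params$r
  if (is.null(covariate_mean)) covariate_mean <- rep(0, r)
  if (is.null(covariate_var)) covariate_var <- diag(0, r)
  covariate_var <- as.matrix(covariate_var)
  C <- params$process_noise_cov
  if (r > 0) C <- C + B %*% covariate_var %*% t(B)
  vecG <- solve(diag(q * q) - kronecker(F, F), as.vector(C))
  G <- matrix(vecG, q, q)
  G <- 0.5 * (G + t(G))
  drift <- params$dyn_intercept
  if (r > 0) drift <- drift + as.numeric(B %*% covariate_mean)
  mu <- as.numeric(solve(diag(q) - F, drift))
  list(mean = mu, cov = G)
}

# Initial state distribution used for simulation and estimation when the
# model does not pin one down: stationary solution given covariate moments.
init_state <- function(params, covariate_mean = NULL, covariate_var = NULL) {
  if (!is.null(params$init_mean) && !is.null(params$init_cov)) {
    return(list(mean = params$init_mean, cov = params$init_cov))
  }
  sm <- stationary_moments(params, covariate_mean, covariate_var)
  if (!is.null(params$init_mean)) sm$mean <- params$init_mean
  if (!is.null(params$init_cov)) sm$cov <- params$init_cov
  sm
}
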