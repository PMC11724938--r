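# Maximum likelihood estimation by prediction error decomposition.

# Moment-based starting values, block by block: indicator means for
# intercepts, ones for free loadings, half the observed indicator variance
# split between measurement and process noise, the anchor indicator's
# lag-1 autocorrelation for autoregressive coefficients, 0 for covariate
# effects and covariances.
start_values <- function(template, panel) {
  fm <- template$free
  pv <- panel_vars(panel)
  Y <- as.matrix(panel[pv$y])
  ym <- colMeans(Y, na.rm = TRUE)
  yv <- apply(Y, 2, stats::var, na.rm = TRUE)
  # anchor indicator per factor: first row with a fixed unit loading
  anchors <- integer(template$q)
  for (j in seq_len(template$q)) {
    cand <- which(template$loadings[, j] == 1)
    anchors[j] <- if (length(cand)) cand[1] else which.max(
      abs(template$loadings[, j]))
  }
  pb <- person_bounds(panel)
  ar_start <- vapply(anchors, function(a) {
    v <- Y[, a]
    lag <- c(NA, v[-length(v)]); lag[pb$first] <- NA
    r <- suppressWarnings(stats::cor(v, lag, use = "pairwise"))
    if (!is.finite(r)) 0.1 else min(max(r, 0.05), 0.9)
  }, numeric(1))
  th <- numeric(nrow(fm))
  for (k in seq_len(nrow(fm))) {
    th[k] <- switch(fm$block[k],
      transition = if (fm$row[k] == fm$col[k]) ar_start[fm$row[k]] else 0,
      dyn_covariate_weights = 0,
      dyn_intercept = 0,
      process_noise_cov = if (fm$row[k] == fm$col[k])
        0.5 * yv[anchors[fm$row[k]]] else 0,
      meas_intercept = ym[fm$row[k]],
      loadings = 1,
      meas_covariate_weights = 0,
      meas_noise_cov = 0.5 * yv[fm$row[k]])
  }
  stats::setNames(th, fm$name)
}

# forward-difference Hessian of f at x (symmetric by construction)
fd_hessian <- function(f, x, rel_step = 1e-4) {
  k <- length(x)
  h <- rel_step * pmax(abs(x), 1)
  f0 <- f(x)
  fi <- numeric(k)
  for (i in seq_len(k)) {
    xi <- x; xi[i] <- xi[i] + h[i]
    fi[i] <- f(xi)
  }
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      xij <- x; xij[i] <- xij[i] + h[i]; xij[j] <- xij[j] + h[j]
      H[i, j] <- H[j, i] <- (f(xij) - fi[i] - fi[j] + f0) / (h[i] * h[j])
    }
  }
  H
}

#' Fit a state-space model by maximum likelihood
#'
#' Minimizes the prediction-error-decomposition negative log-likelihood
#' over the free parameters of `template`. Variances are optimized on the
#' log scale and the process noise covariance through its log-Cholesky
#' factor; the initial state distribution is held at the stationary
#' solution implied by the current parameters (which confines the search
#' to the stable region). Standard errors come from the inverse numerical
#' Hessian on the natural parameter scale.
#'
#' @param data long-format panel (missing y handled by the filter; rows
#'   with missing covariates are excluded from the likelihood).
#' @param template a `mifs_model` with a non-empty free map; its entries
#'   provide the fixed values of non-free parameters.
#' @param start optional named vector of natural-scale starting values
#'   (defaults to moment-based starts).
#' @param hessian compute standard errors (skip to save time when only
#'   point estimates are needed, e.g. the factor-score stage).
#' @param control passed to [stats::optim()] (`maxit`, `reltol`).
#' @param restarts number of jittered restarts if the optimizer reports
#'   nonconvergence.
#' @return object of class `mifs_fit`: list with `estimates`, `se`,
#'   `vcov`, `loglik`, `converged`, `n_used`, `n_excluded`, `model` (the
#'   template at the estimates), and `npar`.
#' @export
fit_ml <- function(data, template, start = NULL, hessian = TRUE,
                   control = list(), restarts = 3) {
  stopifnot(inherits(template, "mifs_model"))
  if (is.null(template$free) || nrow(template$free) == 0) {
    stop("template has no free parameters")
  }
  prep <- prep_ss_data(template, data)
  if (all(is.na(prep$Y))) stop("no usable occasions in data")
  ctrl <- utils::modifyList(list(maxit = 500, reltol = 1e-10), control)

  th0 <- if (is.null(start)) start_values(template, prep$panel) else {
    s <- start_values(template, prep$panel)
    s[names(start)] <- start
    s
  }
  obj_theta <- function(th) {
    if (any(!is.finite(th))) return(1e10)
    m <- tryCatch(set_theta(template, th), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    out <- tryCatch(ss_run(m, prep, mode = 0), error = function(e) NULL)
    if (is.null(out) || !isTRUE(out$ok) || !is.finite(out$nll)) return(1e10)
    out$nll
  }
  obj_phi <- function(phi) {
    th <- tryCatch(phi_to_theta(template, phi), error = function(e) NULL)
    if (is.null(th)) return(1e10)
    obj_theta(th)
  }

  phi0 <- theta_to_phi(template, th0)
  best <- NULL
  for (attempt in 0:restarts) {
    p0 <- if (attempt == 0) phi0 else
      best$par + stats::rnorm(length(phi0), 0, 0.05 * (1 + abs(best$par)))
    opt <- stats::optim(p0, obj_phi, method = "BFGS", control = ctrl)
    if (is.null(best) || opt$value < best$value) best <- opt
    if (best$convergence == 0) break
  }

  theta_hat <- phi_to_theta(template, best$par)
  names(theta_hat) <- template$free$name
  model_hat <- set_theta(template, theta_hat)
  out <- ss_run(model_hat, prep, mode = 0)

  se <- rep(NA_real_, length(theta_hat))
  V <- NULL
  if (hessian) {
    H <- tryCatch(fd_hessian(obj_theta, theta_hat), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V) && all(diag(V) > 0)) {
        se <- sqrt(diag(V))
      } else {
        V <- NULL
        warning("Hessian not positive definite; standard errors unavailable")
      }
    }
  }
  names(se) <- names(theta_hat)
  if (!is_stable(model_hat$transition)) {
    warning("estimated transition matrix is not stable")
  }

  structure(list(
    estimates = theta_hat,
    se = se,
    vcov = V,
    loglik = -best$value,
    converged = best$convergence == 0 && is.finite(best$value),
    n_used = out$nobs_used,
    n_excluded = prep$n_excluded,
    npar = length(theta_hat),
    model = model_hat,
    optim = best[c("convergence", "counts", "value")]
  ), class = "mifs_fit")
}

#' @export
print.mifs_fit <- function(x, ...) {
  cat("State-space ML fit:", x$npar, "free parameters, logLik =",
      format(x$loglik, digits = 6),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  tab <- data.frame(estimate = x$estimates, se = x$se)
  print(round(tab, 4))
  invisible(x)
}

#' Normal-theory confidence intervals for a single ML fit
#' @param fit a `mifs_fit`.
#' @param level confidence level.
#' @return data.frame parameter, estimate, se, ci_lo, ci_hi.
#' @export
fit_ci <- function(fit, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(parameter = names(fit$estimates),
             estimate = unname(fit$estimates),
             se = unname(fit$se),
             ci_lo = unname(fit$estimates - zq * fit$se),
             ci_hi = unname(fit$estimates + zq * fit$se),
             row.names = NULL)
}

#' Longitudinal factor scores from an incomplete panel
#'
#' Fits a covariate-free measurement + dynamic model to the (possibly
#' incomplete) panel by ML, then runs the fixed-interval smoother at the
#' estimates. Scores are defined at every occasion, including fully
#' missing ones, where they equal the model-implied conditional path.
#'
#' @param data long-format panel.
#' @param template_no_covariates a `mifs_model` whose covariate effect
#'   blocks are zero and not estimated (e.g.
#'   `pfa_template(covariates = FALSE)`).
#' @param hessian compute SEs for the score-stage fit (default `FALSE`).
#' @param ... passed to [fit_ml()].
#' @return list with `scores` (smoothed latent paths, one column per
#'   factor) and `fit` (the score-stage `mifs_fit`).
#' @export
estimate_factor_scores <- function(data, template_no_covariates,
                                   hessian = FALSE, ...) {
  tpl <- template_no_covariates
  if (any(tpl$dyn_covariate_weights != 0) ||
      any(tpl$meas_covariate_weights != 0) ||
      any(tpl$free$block %in%
            c("dyn_covariate_weights", "meas_covariate_weights"))) {
    stop("factor-score template must exclude covariate effects")
  }
  fit <- fit_ml(data, tpl, hessian = hessian, ...)
  scores <- kalman_smoother(fit$model, data)
  list(scores = scores, fit = fit)
}
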