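# R-side bridge to the compiled state-space recursions.
#
# All covariate effects are folded into per-row intercepts before calling
# the compiled code: CA[t, ] = tau + A x_t and CB[t, ] = alpha + B x_t.
# Occasions with missing covariates (when the model uses covariates) are
# excluded from the likelihood: their y rows are treated as fully missing
# and the covariate values are replaced by observed column means for the
# state propagation only.

prep_ss_data <- function(template, panel) {
  panel <- validate_panel(panel)
  pv <- panel_vars(panel)
  p <- template$p; r <- template$r
  if (length(pv$y) != p) {
    stop("panel has ", length(pv$y), " y columns but model expects ", p)
  }
  Y <- as.matrix(panel[pv$y])
  uses_x <- r > 0 &&
    (any(template$dyn_covariate_weights != 0) ||
       any(template$meas_covariate_weights != 0) ||
       (!is.null(template$free) &&
          any(template$free$block %in%
                c("dyn_covariate_weights", "meas_covariate_weights"))))
  X <- NULL
  n_excluded <- 0L
  if (uses_x) {
    if (length(pv$x) < r) stop("panel lacks covariate columns x1..x", r)
    X <- as.matrix(panel[pv$x[seq_len(r)]])
    bad <- rowSums(is.na(X)) > 0
    n_excluded <- sum(bad)
    if (n_excluded > 0) {
      Y[bad, ] <- NA_real_
      cm <- colMeans(X, na.rm = TRUE)
      for (j in seq_len(r)) X[is.na(X[, j]), j] <- cm[j]
    }
  }
  idx <- panel_index(panel)
  balanced <- length(unique(idx$len)) == 1L
  list(panel = panel, Y = Y, X = X, idx = idx, uses_x = uses_x,
       n_excluded = n_excluded, balanced = balanced,
       xmean = if (uses_x) colMeans(X) else NULL,
       xcov = if (uses_x && nrow(X) > 1) stats::cov(X) else
         if (uses_x) diag(0, r) else NULL,
       p = p, n = nrow(Y))
}

ss_intercepts <- function(params, prep) {
  n <- prep$n
  CA <- matrix(params$meas_intercept, n, params$p, byrow = TRUE)
  CB <- matrix(params$dyn_intercept, n, params$q, byrow = TRUE)
  if (prep$uses_x) {
    CA <- CA + prep$X %*% t(params$meas_covariate_weights)
    CB <- CB + prep$X %*% t(params$dyn_covariate_weights)
  }
  list(CA = CA, CB = CB)
}

ss_init <- function(params, prep) {
  init_state(params, prep$xmean, prep$xcov)
}

# mode: 0 loglik, 1 filter, 2 smooth. Returns raw C++ list.
ss_run <- function(params, prep, mode, fast_ok = (mode == 0)) {
  ic <- tryCatch(ss_init(params, prep), error = function(e) NULL)
  if (is.null(ic)) return(list(nll = Inf, ok = FALSE, nobs_used = 0L))
  cc <- ss_intercepts(params, prep)
  if (fast_ok && prep$balanced && !anyNA(prep$Y)) {
    Tn <- prep$idx$len[1]
    N <- length(prep$idx$ids)
    Yadj <- aperm(array(t(prep$Y - cc$CA), dim = c(prep$p, Tn, N)),
                  c(1, 3, 2))
    CBc <- aperm(array(t(cc$CB), dim = c(params$q, Tn, N)), c(1, 3, 2))
    out <- .kf_loglik_complete(Yadj, CBc, params$transition,
                               params$process_noise_cov, params$loadings,
                               params$meas_noise_cov, ic$mean, ic$cov)
    out$nobs_used <- as.integer(N * Tn)
    return(out)
  }
  .kf_core(prep$Y, cc$CA, cc$CB, prep$idx$start, prep$idx$len,
           params$transition, params$process_noise_cov, params$loadings,
           params$meas_noise_cov, ic$mean, ic$cov, as.integer(mode))
}

latent_df <- function(prep, mean_mat, cov_cube, kind) {
  q <- ncol(mean_mat)
  out <- data.frame(id = prep$panel$id, time = prep$panel$time)
  for (j in seq_len(q)) out[[paste0("eta", j)]] <- mean_mat[, j]
  attr(out, "kind") <- kind
  attr(out, "cov") <- cov_cube
  out
}

#' Negative log-likelihood by prediction error decomposition
#'
#' The Gaussian log-likelihood of a panel under a state-space model,
#' accumulated from Kalman-filter innovations. Occasions with partially
#' missing indicators contribute only their observed rows; fully missing
#' occasions contribute nothing; occasions with missing covariates (for
#' covariate-using models) are excluded.
#'
#' @param params a `mifs_model`.
#' @param data long-format panel.
#' @return the negative log-likelihood (scalar) with attributes `n_used`
#'   (occasions entering the likelihood) and `n_excluded`.
#' @export
neg_loglik <- function(params, data) {
  prep <- prep_ss_data(params, data)
  out <- ss_run(params, prep, mode = 0)
  if (!isTRUE(out$ok)) {
    warning("likelihood not finite (non-PD innovation covariance)")
  }
  structure(out$nll, n_used = out$nobs_used, n_excluded = prep$n_excluded)
}

#' Kalman filter: conditional latent states given the past
#'
#' Standard linear Kalman filter per person, returning
#' \eqn{E[\eta_t | y_{1..t}]} and \eqn{Cov[\eta_t | y_{1..t}]}. Occasions
#' with partially missing indicators use only the observed measurement
#' rows; fully missing occasions perform the time update only.
#'
#' @param params a `mifs_model`.
#' @param data long-format panel.
#' @param innovations also return per-occasion one-step prediction errors
#'   and their covariances (list columns).
#' @return data.frame id, time, eta1..etaq with attributes `cov`
#'   (q x q x n array), `kind = "filtered"`, `loglik`, and optionally
#'   `innovations`.
#' @export
kalman_filter <- function(params, data, innovations = FALSE) {
  prep <- prep_ss_data(params, data)
  out <- ss_run(params, prep, mode = 1, fast_ok = FALSE)
  if (!isTRUE(out$ok)) {
    stop("singular innovation covariance at panel row ", out$bad_row)
  }
  res <- latent_df(prep, out$mean, out$cov, "filtered")
  attr(res, "loglik") <- -out$nll
  attr(res, "n_excluded") <- prep$n_excluded
  if (innovations) {
    attr(res, "innovations") <- compute_innovations(params, prep, out)
  }
  res
}

compute_innovations <- function(params, prep, filt) {
  cc <- ss_intercepts(params, prep)
  ic <- ss_init(params, prep)
  n <- prep$n
  v <- vector("list", n); S <- vector("list", n)
  starts <- prep$idx$start + 1L
  for (i in seq_along(prep$idx$ids)) {
    s <- starts[i]; Ti <- prep$idx$len[i]
    for (t in seq_len(Ti)) {
      k <- s + t - 1L
      if (t == 1L) {
        a_pred <- ic$mean; P_pred <- ic$cov
      } else {
        a_pred <- cc$CB[k, ] + params$transition %*% filt$mean[k - 1L, ]
        P_pred <- params$transition %*% filt$cov[, , k - 1L] %*%
          t(params$transition) + params$process_noise_cov
      }
      obs <- which(!is.na(prep$Y[k, ]))
      if (length(obs)) {
        Lo <- params$loadings[obs, , drop = FALSE]
        v[[k]] <- prep$Y[k, obs] - cc$CA[k, obs] -
          as.numeric(Lo %*% a_pred)
        S[[k]] <- Lo %*% P_pred %*% t(Lo) +
          params$meas_noise_cov[obs, obs, drop = FALSE]
      } else {
        v[[k]] <- numeric(0); S[[k]] <- matrix(0, 0, 0)
      }
    }
  }
  list(v = v, S = S)
}

#' Fixed-interval (RTS) Kalman smoother
#'
#' Backward Rauch-Tung-Striebel pass giving \eqn{E[\eta_t | y_{1..T_i}]}
#' and its covariance at every occasion, including fully missing ones.
#' With a null transition matrix this reduces to the classical regression
#' factor-score estimator applied occasion by occasion.
#'
#' @inheritParams kalman_filter
#' @return data.frame as [kalman_filter()] with `kind = "smoothed"`.
#' @export
kalman_smoother <- function(params, data) {
  prep <- prep_ss_data(params, data)
  out <- ss_run(params, prep, mode = 2, fast_ok = FALSE)
  if (!isTRUE(out$ok)) {
    stop("singular innovation covariance at panel row ", out$bad_row)
  }
  res <- latent_df(prep, out$mean, out$cov, "smoothed")
  attr(res, "loglik") <- -out$nll
  attr(res, "n_excluded") <- prep$n_excluded
  res
}
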