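#' Default covariate generator: one binary, remaining continuous
#'
#' Draws `x1 ~ Bernoulli(0.5)` and any further columns from the standard
#' normal, i.i.d. over persons and occasions.
#'
#' @param n number of rows.
#' @param r number of covariate columns.
#' @return n x r numeric matrix.
#' @export
default_covariate_gen <- function(n, r) {
  if (r == 0) return(matrix(numeric(0), n, 0))
  X <- matrix(stats::rnorm(n * r), n, r)
  X[, 1] <- stats::rbinom(n, 1, 0.5)
  X
}

#' Default auxiliary generator: Uniform(-3, 3)
#' @param n number of rows.
#' @param s number of auxiliary columns.
#' @return n x s numeric matrix.
#' @export
default_aux_gen <- function(n, s = 2) {
  matrix(stats::runif(n * s, -3, 3), n, s)
}

#' Simulate a complete panel from a state-space model
#'
#' Generates latent trajectories \eqn{\eta_t = \alpha + F\eta_{t-1} + B x_t
#' + \zeta_t} and indicators \eqn{y_t = \tau + \Lambda\eta_t + A x_t +
#' \epsilon_t} for `n_persons` independent persons over `n_times` equally
#' spaced occasions. The initial state is drawn from the model's initial
#' distribution; when that is unspecified the stationary distribution
#' implied by the parameters and the empirical covariate moments is used.
#'
#' @param params a `mifs_model`; the transition matrix must be stable
#'   unless `allow_unstable = TRUE`.
#' @param n_persons,n_times panel dimensions.
#' @param covariate_gen function(n, r) returning the covariate matrix;
#'   default [default_covariate_gen()].
#' @param aux_gen function(n, s) for auxiliaries; default
#'   [default_aux_gen()] with `n_aux` columns.
#' @param n_aux number of auxiliary columns (default 2).
#' @param seed integer seed; the output is deterministic given it.
#' @param burn_in optional number of pre-sample iterations run before the
#'   first retained occasion (default 0; the stationary initial
#'   distribution makes burn-in unnecessary).
#' @param allow_unstable skip the stability check (requires explicit
#'   `init_mean`/`init_cov` in `params`).
#' @return list with `panel` (complete long-format data.frame) and
#'   `latent` (data.frame id, time, eta1..etaq of the true states, class
#'   attribute `kind = "true"`).
#' @export
simulate_panel <- function(params, n_persons = 30, n_times = 100,
                           covariate_gen = default_covariate_gen,
                           aux_gen = default_aux_gen, n_aux = 2,
                           seed = NULL, burn_in = 0,
                           allow_unstable = FALSE) {
  stopifnot(inherits(params, "mifs_model"))
  if (!allow_unstable && !is_stable(params$transition)) {
    stop("transition matrix is unstable; set allow_unstable = TRUE ",
         "and provide init_mean/init_cov to override")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- params$p; q <- params$q; r <- params$r
  n <- n_persons * n_times

  X <- covariate_gen(n, r)
  if (r > 0) {
    X <- as.matrix(X)
    stopifnot(nrow(X) == n, ncol(X) == r)
  }
  Z <- if (n_aux > 0) as.matrix(aux_gen(n, n_aux)) else
    matrix(numeric(0), n, 0)

  if (allow_unstable) {
    init <- list(mean = params$init_mean, cov = params$init_cov)
    if (is.null(init$mean) || is.null(init$cov)) {
      stop("allow_unstable requires explicit init_mean and init_cov")
    }
  } else {
    xm <- if (r > 0) colMeans(X) else NULL
    xv <- if (r > 0) stats::cov(X) else NULL
    if (r > 0 && n == 1) xv <- diag(0, r)
    init <- init_state(params, xm, xv)
  }

  L_init <- safe_chol_lower(init$cov)
  L_q <- safe_chol_lower(params$process_noise_cov)
  L_r <- safe_chol_lower(params$meas_noise_cov)

  eta <- matrix(0, n, q)
  Y <- matrix(0, n, p)
  row0 <- 0L
  for (i in seq_len(n_persons)) {
    e <- init$mean + L_init %*% stats::rnorm(q)
    for (b in seq_len(burn_in)) {
      e <- params$dyn_intercept + params$transition %*% e +
        L_q %*% stats::rnorm(q)
    }
    for (t in seq_len(n_times)) {
      k <- row0 + t
      xt <- if (r > 0) X[k, ] else numeric(0)
      if (t > 1L || burn_in > 0) {
        e <- params$dyn_intercept + params$transition %*% e +
          L_q %*% stats::rnorm(q)
        if (r > 0) e <- e + params$dyn_covariate_weights %*% xt
      }
      eta[k, ] <- e
      mu <- params$meas_intercept + params$loadings %*% e
      if (r > 0) mu <- mu + params$meas_covariate_weights %*% xt
      Y[k, ] <- mu + L_r %*% stats::rnorm(p)
    }
    row0 <- row0 + n_times
  }

  panel <- data.frame(id = rep(seq_len(n_persons), each = n_times),
                      time = rep(seq_len(n_times), n_persons))
  for (j in seq_len(p)) panel[[paste0("y", j)]] <- Y[, j]
  for (j in seq_len(r)) panel[[paste0("x", j)]] <- X[, j]
  for (j in seq_len(ncol(Z))) panel[[paste0("z", j)]] <- Z[, j]

  latent <- data.frame(id = panel$id, time = panel$time)
  for (j in seq_len(q)) latent[[paste0("eta", j)]] <- eta[, j]
  attr(latent, "kind") <- "true"

  list(panel = panel, latent = latent)
}

# lower Cholesky factor that tolerates zero / PSD matrices
safe_chol_lower <- function(S) {
  S <- as.matrix(S)
  if (all(S == 0)) return(S * 0)
  t(suppressWarnings(chol(S + diag(1e-12, nrow(S)))))
}
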