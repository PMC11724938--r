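# state-space core: stability, stationary moments, simulation, filter,
# smoother, likelihood, ML estimation

test_that("is_stable follows the eigenvalue modulus criterion", {
  expect_true(is_stable(matrix(0.7)))
  expect_false(is_stable(matrix(1.0)))
  # eigenvalues 0.5 +/- sqrt(0.06): moduli < 1
  expect_true(is_stable(matrix(c(0.5, -0.3, -0.2, 0.5), 2, 2)))
  expect_false(is_stable(matrix(c(1.1, 0, 0, 0.2), 2, 2)))
})

test_that("stationary moments match closed forms and Lyapunov iteration", {
  # AR(1): var = q / (1 - ar^2)
  m <- scalar_model(ar = 0.5, q_var = 2)
  sm <- stationary_moments(m)
  expect_equal(sm$cov[1, 1], 2 / (1 - 0.25), tolerance = 1e-12)

  # F = 0: Gamma = process noise covariance exactly
  m0 <- ident_model(ar = 0)
  expect_equal(stationary_moments(m0)$cov, diag(c(1, 2)),
               tolerance = 1e-12)

  # bivariate preset with covariate moments: brute-force fixed-point
  # iteration of Gamma <- F Gamma F' + C run to 1e-12
  tpl <- pfa_template("low")
  V <- diag(c(0.25, 1))
  mu_x <- c(0.5, 0)
  sm <- stationary_moments(tpl, mu_x, V)
  C <- tpl$dyn_covariate_weights %*% V %*% t(tpl$dyn_covariate_weights) +
    tpl$process_noise_cov
  G <- diag(0, 2)
  for (i in 1:2000) {
    G_new <- tpl$transition %*% G %*% t(tpl$transition) + C
    if (max(abs(G_new - G)) < 1e-14) break
    G <- G_new
  }
  expect_equal(sm$cov, G, tolerance = 1e-10)
  expect_error(stationary_moments(scalar_model(ar = 1.02)), "unstable")
})

test_that("noise-free simulation sits at the deterministic fixed point", {
  m <- model_params(
    transition = diag(0.5, 2), dyn_intercept = c(0, 0),
    dyn_covariate_weights = matrix(0, 2, 2),
    process_noise_cov = diag(0, 2),
    meas_intercept = rep(3, 4), loadings = rbind(diag(2), diag(2)),
    meas_covariate_weights = matrix(0, 4, 2),
    meas_noise_cov = diag(0, 4),
    init_mean = c(0, 0), init_cov = diag(0, 2))
  sim <- simulate_panel(m, 3, 10, seed = 1)
  expect_true(all(abs(as.matrix(sim$panel[paste0("y", 1:4)]) - 3) < 1e-12))
})

test_that("simulated latent moments match the stationary oracle", {
  tpl <- pfa_template("low")
  sim <- simulate_panel(tpl, 200, 500, seed = 42)
  E <- as.matrix(sim$latent[c("eta1", "eta2")])
  X <- as.matrix(sim$panel[c("x1", "x2")])
  sm <- stationary_moments(tpl, colMeans(X), stats::cov(X))
  n_eff <- 200 * 500 / 10   # conservative for autocorrelated draws
  for (j in 1:2) {
    se_mean <- sqrt(sm$cov[j, j] / n_eff)
    expect_lt(abs(mean(E[, j]) - sm$mean[j]), 3 * se_mean)
    se_var <- sm$cov[j, j] * sqrt(2 / n_eff)
    expect_lt(abs(stats::var(E[, j]) - sm$cov[j, j]), 3 * se_var)
  }
  # empirical lag-1 autocorrelation of eta1 vs model-implied value
  G <- sm$cov
  lag1 <- tpl$transition %*% G    # Cov(eta_t, eta_{t-1}) = F Gamma
  r_model <- lag1[1, 1] / G[1, 1]
  e1 <- matrix(E[, 1], nrow = 500)
  r_emp <- stats::cor(as.vector(e1[-1, ]), as.vector(e1[-500, ]))
  expect_lt(abs(r_emp - r_model), 3 / sqrt(n_eff))
})

test_that("filter reduces to exact measurement in the noise-free limit", {
  m <- ident_model(r_var = 1e-12)
  sim <- simulate_panel(m, 2, 20, seed = 7)
  kf <- kalman_filter(m, sim$panel)
  expect_lt(max(abs(kf$eta1 - (sim$panel$y1 - 1))), 1e-6)
  expect_lt(max(abs(kf$eta2 - (sim$panel$y2 + 1))), 1e-6)
})

test_that("fully missing panel propagates the prior mean", {
  m <- scalar_model(ar = 0.6, q_var = 1)
  m$dyn_intercept <- 0.5
  m$init_mean <- 2; m$init_cov <- matrix(1)
  panel <- data.frame(id = 1, time = 1:5, y1 = NA_real_)
  kf <- kalman_filter(m, panel)
  expected <- numeric(5); expected[1] <- 2
  for (t in 2:5) expected[t] <- 0.5 + 0.6 * expected[t - 1]
  expect_equal(kf$eta1, expected, tolerance = 1e-12)
})

test_that("scalar filter matches a hand-unrolled recursion", {
  m <- scalar_model(ar = 0.8, q_var = 0.5, lam = 1.5, r_var = 0.7,
                    tau = 0.3)
  m$init_mean <- 0.2; m$init_cov <- matrix(1.1)
  y <- c(1.0, -0.4, 2.2)
  panel <- data.frame(id = 1, time = 1:3, y1 = y)
  kf <- kalman_filter(m, panel)
  nll <- neg_loglik(m, panel)

  a <- 0.2; P <- 1.1; ll <- 0
  af <- numeric(3); Pf <- numeric(3)
  for (t in 1:3) {
    if (t > 1) { a <- 0.8 * a; P <- 0.64 * P + 0.5 }
    v <- y[t] - 0.3 - 1.5 * a
    S <- 1.5^2 * P + 0.7
    ll <- ll - 0.5 * (log(2 * pi) + log(S) + v^2 / S)
    K <- P * 1.5 / S
    a <- a + K * v
    P <- (1 - K * 1.5) * P
    af[t] <- a; Pf[t] <- P
  }
  expect_equal(kf$eta1, af, tolerance = 1e-10)
  expect_equal(as.numeric(attr(kf, "cov")[1, 1, ]), Pf, tolerance = 1e-10)
  expect_equal(as.numeric(nll), -ll, tolerance = 1e-8)
})

test_that("smoother equals regression factor scores when F = 0", {
  tpl <- pfa_template("low", covariates = FALSE)
  tpl$transition <- matrix(0, 2, 2)
  tpl$init_mean <- NULL; tpl$init_cov <- NULL
  sim <- simulate_panel(tpl, 3, 15, seed = 11)
  sm <- kalman_smoother(tpl, sim$panel)
  Sg <- stationary_moments(tpl)$cov     # = process noise cov at F = 0
  Lam <- tpl$loadings
  W <- Sg %*% t(Lam) %*% solve(Lam %*% Sg %*% t(Lam) + tpl$meas_noise_cov)
  Y <- as.matrix(sim$panel[paste0("y", 1:6)])
  reg <- t(W %*% (t(Y) - tpl$meas_intercept))
  expect_lt(max(abs(as.matrix(sm[c("eta1", "eta2")]) - reg)), 1e-8)
})

test_that("smoother terminal point equals the filter, and never inflates
           uncertainty", {
  tpl <- pfa_template("low")
  sim <- simulate_panel(tpl, 3, 25, seed = 13)
  p <- sim$panel
  p$y2[sample.int(75, 20)] <- NA    # ragged missingness
  kf <- kalman_filter(tpl, p)
  ks <- kalman_smoother(tpl, p)
  last <- which(p$time == 25)
  expect_equal(as.matrix(ks[last, c("eta1", "eta2")]),
               as.matrix(kf[last, c("eta1", "eta2")]), tolerance = 1e-10)
  cf <- attr(kf, "cov"); cs <- attr(ks, "cov")
  for (k in seq_len(nrow(p))) {
    d <- eigen(cf[, , k] - cs[, , k], symmetric = TRUE,
               only.values = TRUE)$values
    expect_gt(min(d), -1e-10)   # smoothed cov <= filtered cov (Loewner)
  }
})

test_that("likelihood matches closed forms and is additive over persons", {
  # single occasion: marginal normal density
  m <- scalar_model(ar = 0.3, q_var = 1, lam = 1.2, r_var = 0.5, tau = 1)
  m$init_mean <- 0.4; m$init_cov <- matrix(2)
  panel <- data.frame(id = 1, time = 1, y1 = 0.9)
  nll <- neg_loglik(m, panel)
  expect_equal(as.numeric(nll),
               -stats::dnorm(0.9, 1 + 1.2 * 0.4, sqrt(1.2^2 * 2 + 0.5),
                             log = TRUE), tolerance = 1e-10)

  # duplicating every person doubles the value exactly (initial state
  # pinned so the likelihood is a fixed function of the data)
  tpl <- pfa_template("low")
  sm <- stationary_moments(tpl, c(0.5, 0), diag(c(0.25, 1)))
  tpl$init_mean <- sm$mean; tpl$init_cov <- sm$cov
  sim <- simulate_panel(tpl, 4, 20, seed = 17)
  p2 <- sim$panel
  p2$id <- p2$id + 100
  both <- rbind(sim$panel, p2)
  expect_equal(2 * as.numeric(neg_loglik(tpl, sim$panel)),
               as.numeric(neg_loglik(tpl, both)), tolerance = 1e-8)

  # scalar AR(1) observed directly: exact Gaussian AR(1) likelihood
  ar <- 0.7; qv <- 1.3
  m <- scalar_model(ar = ar, q_var = qv, lam = 1, r_var = 0, tau = 0)
  sim <- simulate_panel(m, 2, 30, seed = 19)
  nll <- neg_loglik(m, sim$panel)
  ll <- 0
  for (i in 1:2) {
    y <- sim$panel$y1[sim$panel$id == i]
    v0 <- qv / (1 - ar^2)
    ll <- ll + stats::dnorm(y[1], 0, sqrt(v0), log = TRUE) +
      sum(stats::dnorm(y[-1], ar * y[-30], sqrt(qv), log = TRUE))
  }
  expect_equal(as.numeric(nll), -ll, tolerance = 1e-8)
})

test_that("likelihood is invariant to person order and indicator
           permutation", {
  tpl <- pfa_template("low")
  sim <- simulate_panel(tpl, 5, 15, seed = 23)
  p <- sim$panel
  p$y3[c(4, 9, 30)] <- NA
  base <- as.numeric(neg_loglik(tpl, p))
  # reversed person order
  prev <- p[order(-p$id, p$time), ]
  expect_equal(as.numeric(neg_loglik(tpl, prev)), base, tolerance = 1e-9)
  # permute indicator columns together with matching parameter rows
  perm <- c(3, 1, 2, 6, 4, 5)
  tpl2 <- tpl
  tpl2$meas_intercept <- tpl$meas_intercept[perm]
  tpl2$loadings <- tpl$loadings[perm, ]
  tpl2$meas_noise_cov <- tpl$meas_noise_cov[perm, perm]
  tpl2$meas_covariate_weights <- tpl$meas_covariate_weights[perm, ]
  p3 <- p
  p3[paste0("y", 1:6)] <- p[paste0("y", perm)]
  expect_equal(as.numeric(neg_loglik(tpl2, p3)), base, tolerance = 1e-9)
})

test_that("profile ML recovers a single free AR parameter", {
  tpl <- pfa_template("low")
  free_a1 <- tpl
  free_a1$free <- free_map("a1", "transition", 1, 1)
  sim <- simulate_panel(tpl, 30, 100, seed = 29)
  fit <- fit_ml(sim$panel, free_a1, hessian = FALSE)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["a1"]] - 0.5), 0.05)
})

test_that("full ML fit converges to a stationary optimum and recovers
           the generating parameters", {
  tpl <- pfa_template("low")
  sim <- simulate_panel(tpl, 30, 100, seed = 31)
  fit <- fit_ml(sim$panel, tpl)
  expect_true(fit$converged)
  expect_equal(fit$n_used, 3000)
  # refit from the optimum: loglik change below 1e-6
  fit2 <- fit_ml(sim$panel, tpl, start = fit$estimates, restarts = 0)
  expect_lt(abs(fit2$loglik - fit$loglik), 1e-6)
  # estimates within 4 SE of truth for most parameters on one panel
  truth <- true_values(tpl)
  zs <- abs(fit$estimates - truth) / fit$se
  expect_lt(stats::median(zs), 2)
  expect_true(all(is.finite(fit$se)))
})

test_that("factor scores stay defined for persons with no data", {
  tpl <- pfa_template("low", covariates = FALSE)
  sim <- simulate_panel(tpl, 4, 30, seed = 37)
  p <- sim$panel
  p[p$id == 2, paste0("y", 1:6)] <- NA
  sc <- kalman_smoother(tpl, p)
  expect_false(anyNA(sc[c("eta1", "eta2")]))
  # with zero dynamic intercept the unconditional path is the zero mean
  expect_lt(max(abs(sc$eta1[p$id == 2])), 1e-9)
})
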