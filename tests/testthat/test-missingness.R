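# logistic NMAR/MAR masking, calibration and diagnostics

make_complete <- function(n_persons = 10, n_times = 100, seed = 101) {
  tpl <- pfa_template("low")
  simulate_panel(tpl, n_persons, n_times, seed = seed)
}

test_that("constant-probability masking hits the intended rate", {
  sim <- make_complete(10, 150, seed = 5)
  spec <- missingness_spec("item_dependent", phi1 = 0, phi2 = 0,
                           phi3 = c(y1 = 0), target_rate = 0.3)
  spec$phi0 <- c(y1 = log(0.3 / 0.7))
  masked <- apply_item_dependent(sim$panel, spec, seed = 6)
  n <- nrow(masked)
  rate <- mean(is.na(masked$y1))
  expect_lt(abs(rate - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  # other columns untouched
  expect_false(anyNA(masked$y2))
})

test_that("calibrated preset produces ~30% missingness per variable and
           cells are independent given drivers", {
  tpl <- pfa_template("low")
  spec <- calibrate_phi0(missingness_spec("item_dependent"), params = tpl)
  sim <- make_complete(30, 100, seed = 7)
  masked <- apply_item_dependent(sim$panel, spec, seed = 8)
  rates <- missingness_summary(masked)$rates
  expect_true(all(abs(rates - 0.3) < 0.04))
  # joint all-of-y1..y3 missingness ~ product of per-occasion marginals
  truth <- attr(masked, "truth")
  P <- vapply(paste0("y", 1:3), function(v) {
    stats::plogis(spec$phi0[[v]] + spec$phi1 * truth$z1 +
                    spec$phi2 * truth$z2 + spec$phi3[[v]] * truth[[v]])
  }, numeric(nrow(truth)))
  p_joint <- mean(P[, 1] * P[, 2] * P[, 3])
  emp <- mean(rowSums(is.na(masked[paste0("y", 1:3)])) == 3)
  expect_lt(abs(emp - p_joint),
            3 * sqrt(p_joint * (1 - p_joint) / nrow(truth)))
})

test_that("factor-dependent masking is all-or-none per indicator block
           and tracks the latent driver", {
  tpl <- pfa_template("low")
  spec <- calibrate_phi0(missingness_spec("factor_dependent"),
                         params = tpl)
  sim <- make_complete(30, 100, seed = 9)
  masked <- apply_factor_dependent(sim$panel, sim$latent, spec, seed = 10)
  m1 <- rowSums(is.na(masked[paste0("y", 1:3)]))
  m2 <- rowSums(is.na(masked[paste0("y", 4:6)]))
  expect_true(all(m1 %in% c(0, 3)))
  expect_true(all(m2 %in% c(0, 3)))
  rates <- missingness_summary(masked)$rates
  expect_true(all(abs(rates - 0.3) < 0.05))
  # sign checks: phi3 = -0.6 for eta1 (low values masked), +0.6 for eta2
  expect_lt(mean(sim$latent$eta1[m1 == 3]), mean(sim$latent$eta1[m1 == 0]))
  expect_gt(mean(sim$latent$eta2[m2 == 3]), mean(sim$latent$eta2[m2 == 0]))
  # masking never alters retained true values
  truth <- attr(masked, "truth")
  expect_identical(truth, sim$panel)
})

test_that("zero driver coefficients reduce the factor rule to MAR", {
  tpl <- pfa_template("low")
  spec <- missingness_spec("factor_dependent",
                           phi3 = c(eta1 = 0, eta2 = 0, x1 = 0, x2 = 0))
  spec <- calibrate_phi0(spec, params = tpl)
  sim <- make_complete(30, 100, seed = 11)
  masked <- apply_factor_dependent(sim$panel, sim$latent, spec, seed = 12)
  m1 <- is.na(masked$y1)
  # ignorability: masked vs observed true means differ within MC noise
  d <- mean(sim$latent$eta1[m1]) - mean(sim$latent$eta1[!m1])
  se <- stats::sd(sim$latent$eta1) * sqrt(1 / sum(m1) + 1 / sum(!m1))
  expect_lt(abs(d), 3 * se)
})

test_that("MAR location indicators are independent of the data and
           simultaneous mode masks whole blocks", {
  sim <- make_complete(20, 100, seed = 13)
  out <- apply_mar_location(sim$panel, "simultaneous", rate = 0.25,
                            seed = 14)
  m1 <- rowSums(is.na(out$panel[paste0("y", 1:3)]))
  expect_true(all(m1 %in% c(0, 3)))
  expect_equal(m1 == 3, out$indicators$Rloc_eta1 == 1)
  n <- nrow(sim$panel)
  for (v in c("y1", "y4")) {
    r <- stats::cor(out$indicators$Rloc_eta1, sim$panel[[v]])
    expect_lt(abs(r), 3 / sqrt(n))
  }
  out2 <- apply_mar_location(sim$panel, "scattered", rate = 0, seed = 15)
  expect_identical(out2$panel[names(sim$panel)], sim$panel)
  expect_error(apply_mar_location(sim$panel, "scattered", rate = 1.2))
})

test_that("composite-driven masking uses the row mean of the three
           series and hits the target rate", {
  # trivariate observed VAR: identity-like model with 3 indicators
  m <- model_params(
    transition = diag(0.4, 3), dyn_intercept = rep(0, 3),
    dyn_covariate_weights = matrix(0, 3, 0),
    process_noise_cov = diag(2, 3),
    meas_intercept = rep(0, 3), loadings = diag(3),
    meas_covariate_weights = matrix(0, 3, 0),
    meas_noise_cov = diag(1e-8, 3))
  sim <- simulate_panel(m, 20, 100, seed = 16)
  spec <- missingness_spec("composite_dependent", phi3 = c(comp = -0.6))
  spec <- calibrate_phi0(spec, panel = sim$panel)
  masked <- apply_composite_dependent(sim$panel, spec, seed = 17)
  mm <- rowSums(is.na(masked[paste0("y", 1:3)]))
  expect_true(all(mm %in% c(0, 3)))
  expect_lt(abs(mean(mm == 3) - 0.3), 0.03)
  # worked example: composite is exactly the row mean
  tiny <- data.frame(id = 1, time = 1:3, y1 = c(1, 2, 3),
                     y2 = c(2, 2, 2), y3 = c(3, 5, 1))
  expect_equal(rowMeans(tiny[paste0("y", 1:3)]), c(2, 3, 2))
  expect_error(apply_composite_dependent(sim$panel[-3], spec),
               "3 y columns")
})

test_that("calibration solves the analytic case, is symmetric, monotone,
           and transfers out of sample", {
  tpl <- pfa_template("low")
  # all slopes zero: phi0 = logit(rate) exactly
  spec0 <- missingness_spec("item_dependent", phi1 = 0, phi2 = 0,
                            phi3 = c(y1 = 0), target_rate = 0.3)
  cal0 <- calibrate_phi0(spec0, params = tpl)
  expect_equal(unname(cal0$phi0["y1"]), log(0.3 / 0.7), tolerance = 1e-3)

  # symmetric driver: flipping phi3 keeps the achieved rate
  spec_p <- missingness_spec("item_dependent", phi1 = 0, phi2 = 0,
                             phi3 = c(x2 = 0.7))
  spec_m <- missingness_spec("item_dependent", phi1 = 0, phi2 = 0,
                             phi3 = c(x2 = -0.7))
  cal_p <- calibrate_phi0(spec_p, params = tpl)
  cal_m <- calibrate_phi0(spec_m, params = tpl)
  expect_equal(unname(cal_p$phi0["x2"]), unname(cal_m$phi0["x2"]),
               tolerance = 0.02)

  # monotonicity: higher phi0 => higher empirical rate
  sim <- make_complete(10, 100, seed = 18)
  spec <- calibrate_phi0(missingness_spec("item_dependent"), params = tpl)
  up <- spec; up$phi0 <- spec$phi0 + 1
  r0 <- mean(is.na(apply_item_dependent(sim$panel, spec, seed = 19)$y1))
  r1 <- mean(is.na(apply_item_dependent(sim$panel, up, seed = 19)$y1))
  expect_gt(r1, r0)

  # out-of-sample: fresh seeded panel reproduces the target within 0.02
  sim2 <- make_complete(30, 100, seed = 20)
  masked <- apply_item_dependent(sim2$panel, spec, seed = 21)
  rates <- missingness_summary(masked)$rates
  expect_true(all(abs(rates - 0.3) < 0.02 + 3 * sqrt(0.21 / 3000)))

  # unreachable rate errors with the achievable range
  bad <- missingness_spec("item_dependent", phi1 = 1e6, phi2 = 0,
                          phi3 = c(y1 = 0), target_rate = 0.3)
  expect_error(calibrate_phi0(bad, params = tpl), "unreachable")
})

test_that("McKelvey-Zavoina shares match the closed form", {
  expect_warning(
    out0 <- mz_rsquared(list(a = rep(0, 100), b = stats::rnorm(100))),
    "zero-variance")
  expect_equal(out0$share_full[1], 0)
  # phi = 0.6, x ~ U(-3,3): Var = 0.36 * 3 = 1.08
  set.seed(22)
  x <- stats::runif(2e5, -3, 3)
  out <- mz_rsquared(list(t1 = 0.6 * x))
  expect_equal(out$single, 1.08 / (1.08 + pi^2 / 3), tolerance = 0.01)
  # doubling the coefficient increases the single-predictor share
  out2 <- mz_rsquared(list(t1 = 1.2 * x))
  expect_gt(out2$single, out$single)
})

test_that("missingness summary agrees with an independent recount", {
  masked <- fixture_panel()
  s <- missingness_summary(masked)
  pv <- c(paste0("y", 1:6), "x1", "x2")
  expect_equal(unname(s$rates[pv]),
               unname(colMeans(is.na(masked[pv]))))
  complete <- attr(masked, "truth")
  expect_true(all(missingness_summary(complete)$rates == 0))
  full <- complete
  full$y1[] <- NA
  expect_equal(unname(missingness_summary(full)$rates["y1"]), 1)
})
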