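# chained-equations engine, PMM / logistic steps, convergence diagnostic

test_that("design builder assembles the documented predictor pools", {
  masked <- fixture_panel()
  scores <- data.frame(id = masked$id, time = masked$time,
                       eta1 = stats::rnorm(nrow(masked)),
                       eta2 = stats::rnorm(nrow(masked)))
  des <- build_design(masked, scores, imputation_spec(seed = 1))
  # 6 manifest + 2 covariate targets plus their lag targets
  expect_setequal(names(des$targets)[1:8], c(paste0("y", 1:6), "x1", "x2"))
  expect_true(all(paste0("lag_", c(paste0("y", 1:6), "x1", "x2")) %in%
                    names(des$targets)))
  expect_equal(unname(des$targets[["x1"]]), "logistic")
  expect_equal(unname(des$targets[["y1"]]), "pmm")
  # no target predicts itself
  for (v in rownames(des$predictors)) {
    if (v %in% colnames(des$predictors)) {
      expect_false(des$predictors[v, v])
    }
  }
  # factor-scores-only ablation: y targets see no other manifest columns
  des2 <- build_design(masked, scores,
                       imputation_spec(include_other_manifest = FALSE,
                                       seed = 1))
  pool_y1 <- colnames(des2$predictors)[des2$predictors["y1", ]]
  expect_length(intersect(pool_y1, paste0("y", 2:6)), 0)
  expect_true(all(c("fs1", "fs2") %in% pool_y1))
  # scores required iff requested
  expect_error(build_design(masked, NULL, imputation_spec(seed = 1)),
               "factor scores")
})

test_that("PMM imputes observed donor values and finds exact matches", {
  # noiseless linear relation: missing case at x = 5 must receive y(5)
  x <- 1:10
  y <- 2 * x
  tgt <- c(y, NA)
  set.seed(1)
  imp <- pmm_step(tgt, matrix(c(x, 5), ncol = 1), donors = 1)
  expect_equal(imp, 10)

  # support preservation over 100 seeded runs
  for (s in 1:100) {
    set.seed(s)
    n <- 120
    xx <- stats::rnorm(n)
    yy <- 0.8 * xx + stats::rnorm(n, sd = 0.6)
    hole <- sample.int(n, 48)
    tgt <- yy; tgt[hole] <- NA
    imp <- pmm_step(tgt, cbind(xx), donors = 5)
    expect_true(all(imp %in% yy[-hole]))
  }
})

test_that("PMM under MCAR holes with informative predictors is unbiased
           for the masked-cell mean", {
  set.seed(33)
  reps <- 60
  bias <- numeric(reps)
  for (r in seq_len(reps)) {
    n <- 300
    x <- stats::rnorm(n)
    y <- 1 + 2 * x + stats::rnorm(n, sd = 0.5)
    hole <- sample.int(n, 120)
    tgt <- y; tgt[hole] <- NA
    imp <- pmm_step(tgt, cbind(x), donors = 5)
    bias[r] <- mean(imp) - mean(y[hole])
  }
  expect_lt(abs(mean(bias)), 3 * stats::sd(bias) / sqrt(reps))
})

test_that("logistic step handles degenerate and strong-signal cases", {
  n <- 200
  x <- stats::rnorm(n)
  # single observed class imputes that class
  tgt <- c(rep(1, 50), rep(NA, 10))
  expect_warning(imp <- logistic_step(tgt, cbind(stats::rnorm(60))),
                 "single observed class")
  expect_true(all(imp == 1))
  # null coefficients: imputation rate tracks the observed class rate
  set.seed(41)
  y <- stats::rbinom(n, 1, 0.35)
  tgt <- y; tgt[1:60] <- NA
  imps <- replicate(40, mean(logistic_step(tgt, cbind(x))))
  expect_lt(abs(mean(imps) - mean(y[-(1:60)])), 0.1)
  # strong predictor: imputed classes follow the sign rule
  set.seed(43)
  x <- stats::rnorm(n)
  y <- as.numeric(stats::plogis(6 * x) > stats::runif(n))
  tgt <- y; hole <- sort(sample.int(n, 70)); tgt[hole] <- NA
  imp <- suppressWarnings(logistic_step(tgt, cbind(x)))
  agree <- mean(imp == as.numeric(x[hole] > 0))
  expect_gte(agree, 0.8)
})

test_that("engine is the identity on complete data and never touches
           observed cells", {
  tpl <- pfa_template("low")
  sim <- simulate_panel(tpl, 4, 20, seed = 51)
  spec <- imputation_spec(m = 3, n_iter = 2, include_factor_scores = FALSE,
                          seed = 5)
  out <- run_chained_equations(sim$panel, NULL, spec)
  expect_length(out$imputations, 3)
  for (k in 1:3) expect_identical(out$imputations[[k]], sim$panel)
  expect_equal(nrow(out$traces), 0)

  masked <- fixture_panel()
  out2 <- run_chained_equations(masked, NULL,
                                imputation_spec(m = 2, n_iter = 3,
                                                include_factor_scores = FALSE,
                                                seed = 6))
  pvars <- c(paste0("y", 1:6), "x1", "x2")
  for (v in pvars) {
    o <- !is.na(masked[[v]])
    for (k in 1:2) {
      expect_identical(out2$imputations[[k]][[v]][o], masked[[v]][o])
      expect_false(anyNA(out2$imputations[[k]][[v]]))
    }
  }
})

test_that("rhat matches a direct textbook recomputation and flags
           divergent chains", {
  # identical chains with no spread: exactly 1, zero-within flagged
  tr <- expand.grid(chain = 1:3, iteration = 1:10)
  tr$variable <- "v"
  tr$mean <- 1.5
  tr$sd <- 0
  tr$n <- 25
  r <- rhat(tr, type = "means")
  expect_equal(unname(r["v"]), 1)
  expect_equal(attr(r, "zero_within"), "v")
  expect_equal(unname(rhat(tr)["v"]), 1)  # draws convention agrees

  # identical chains with spread: draws statistic is (n-1)/n-close to 1
  tr$sd <- 1
  expect_equal(unname(rhat(tr)["v"]), 1, tolerance = 1e-2)

  # 3 chains x 10 iterations fixture vs independent formulas
  set.seed(61)
  tr$mean <- stats::rnorm(30, rep(c(0, 0.2, -0.1), 10), 0.3)
  M <- matrix(tr$mean, nrow = 10, byrow = TRUE)  # iterations x chains
  W <- mean(apply(M, 2, stats::var))
  B <- 10 * stats::var(colMeans(M))
  expect_equal(unname(rhat(tr, keep_frac = 1, type = "means")["v"]),
               sqrt((9 / 10 * W + B / 10) / W), tolerance = 1e-10)
  Wd <- mean(colMeans(matrix(tr$sd, 10, byrow = TRUE)^2) +
               apply(M, 2, stats::var) * 9 / 10)
  n <- 10 * 25
  expect_equal(unname(rhat(tr, keep_frac = 1)["v"]),
               sqrt((n - 1) / n + stats::var(colMeans(M)) / Wd),
               tolerance = 1e-10)

  # chains imputing in disjoint regions diverge under both conventions
  tr$mean <- rep(c(0, 100, 50), 10) + stats::rnorm(30)
  expect_gt(unname(rhat(tr)["v"]), 1.1)
  expect_gt(unname(rhat(tr, type = "means")["v"]), 1.1)
})
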