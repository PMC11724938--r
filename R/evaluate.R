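# Monte Carlo study harness: replicate {simulate -> mask -> handle -> fit
# -> pool} and summarize estimation performance.

#' Configure a Monte Carlo study condition
#'
#' @param autocorr `"low"` (AR 0.5) or `"high"` (AR 0.7).
#' @param mechanism `"item_dependent"` or `"factor_dependent"`.
#' @param methods subset of `c("LD", "MI-MV", "PMI-MV", "MI-FS")`.
#' @param H number of replications (presets used in this package: smoke =
#'   2, scaled = 50, full = 500); replication h uses seed
#'   `master_seed + h`.
#' @param n_persons,n_times panel dimensions (default 30 x 100).
#' @param imputation a `mifs_imputation_spec` (m, iterations, donors ...).
#' @param master_seed integer master seed.
#' @param null_effects zero out cross-regression and covariate
#'   coefficients in the generating model (type-I-error study).
#' @param target_rate missingness rate per variable (default 0.3).
#' @return object of class `mifs_study_config`.
#' @export
study_config <- function(autocorr = c("low", "high"),
                         mechanism = c("factor_dependent",
                                       "item_dependent"),
                         methods = c("LD", "MI-MV", "PMI-MV", "MI-FS"),
                         H = 2, n_persons = 30, n_times = 100,
                         imputation = imputation_spec(),
                         master_seed = 1L, null_effects = FALSE,
                         target_rate = 0.3) {
  autocorr <- match.arg(autocorr)
  mechanism <- match.arg(mechanism)
  methods <- match.arg(methods, c("LD", "MI-MV", "PMI-MV", "MI-FS"),
                       several.ok = TRUE)
  stopifnot(H >= 1)
  structure(list(autocorr = autocorr, mechanism = mechanism,
                 methods = methods, H = as.integer(H),
                 n_persons = n_persons, n_times = n_times,
                 imputation = imputation,
                 master_seed = as.integer(master_seed),
                 null_effects = null_effects, target_rate = target_rate),
            class = "mifs_study_config")
}

# calibrated missingness spec for a config (fixed calibration seed so the
# intercepts do not adapt to individual replications)
condition_mspec <- function(config) {
  template <- pfa_template(config$autocorr, config$null_effects)
  spec <- missingness_spec(config$mechanism,
                           target_rate = config$target_rate)
  calibrate_phi0(spec, params = template)
}

#' Run one Monte Carlo replication
#'
#' Simulates a complete panel, fits the analysis model to it (the
#' benchmark for SE comparisons), applies the condition's missingness
#' mechanism, and runs each requested handling method on the same masked
#' panel (paired design). MI-MV and PMI-MV share one chained-equations run
#' since they use identical imputation models.
#'
#' @param config a `mifs_study_config`.
#' @param seed replication seed.
#' @param mspec calibrated missingness spec (computed from the config when
#'   `NULL`).
#' @param benchmark fit the complete panel (can be skipped when dSEfull is
#'   not needed).
#' @return list with `benchmark` (`mifs_fit` or NULL), `results` (named
#'   list per method; a failed/nonconvergent method is `NULL` with its
#'   error in `errors`), `truth`, `masked` (the masked panel), `errors`.
#' @export
run_replication <- function(config, seed, mspec = NULL, benchmark = TRUE) {
  if (is.null(mspec)) mspec <- condition_mspec(config)
  template <- pfa_template(config$autocorr, config$null_effects)
  score_template <- pfa_template(config$autocorr, config$null_effects,
                                 covariates = FALSE)
  sim <- simulate_panel(template, config$n_persons, config$n_times,
                        seed = seed)
  bench <- NULL
  if (benchmark) {
    bench <- fit_ml(sim$panel, template)
  }
  masked <- if (config$mechanism == "item_dependent") {
    apply_item_dependent(sim$panel, mspec, seed = seed + 500000L)
  } else {
    apply_factor_dependent(sim$panel, sim$latent, mspec,
                           seed = seed + 500000L)
  }
  ispec <- config$imputation
  ispec$seed <- seed + 700000L

  results <- stats::setNames(vector("list", length(config$methods)),
                             config$methods)
  errors <- list()
  shared_mv <- NULL
  for (meth in config$methods) {
    res <- tryCatch({
      switch(meth,
        "LD" = run_ld(masked, template),
        "MI-MV" = {
          if (is.null(shared_mv)) {
            sp <- ispec; sp$include_factor_scores <- FALSE
            shared_mv <- run_chained_equations(masked, NULL, sp)
          }
          run_mi_mv(masked, template, imputed = shared_mv)
        },
        "PMI-MV" = {
          if (is.null(shared_mv)) {
            sp <- ispec; sp$include_factor_scores <- FALSE
            shared_mv <- run_chained_equations(masked, NULL, sp)
          }
          run_pmi_mv(masked, template, imputed = shared_mv)
        },
        "MI-FS" = run_mi_fs(masked, template, score_template, spec = ispec))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[meth]] <- conditionMessage(res)
      results[meth] <- list(NULL)
    } else {
      results[[meth]] <- res
    }
  }
  list(benchmark = bench, results = results,
       truth = true_values(template), masked = masked, errors = errors)
}

#' Summary statistics of repeated estimates of one parameter
#'
#' bias = mean(est - truth); relative bias = mean((est - truth)/truth)
#' (absent when truth = 0); SE = mean estimated standard error; MCSE =
#' sample SD of the estimates (divisor H - 1); RMSE =
#' sqrt(mean((est - truth)^2)); dSEfull = SE - mean benchmark SE; power =
#' percent of CIs excluding 0; coverage = percent of CIs containing the
#' truth.
#'
#' @param estimates,ses numeric vectors over replications.
#' @param ci_lo,ci_hi confidence bounds over replications.
#' @param truth true parameter value.
#' @param benchmark_ses complete-data SEs (optional, for dSEfull).
#' @return one-row data.frame.
#' @export
performance_measures <- function(estimates, ses, ci_lo, ci_hi, truth,
                                 benchmark_ses = NULL) {
  H <- length(estimates)
  err <- estimates - truth
  data.frame(
    bias = mean(err),
    relative_bias = if (truth != 0) mean(err / truth) else NA_real_,
    se_mean = mean(ses),
    mcse = if (H >= 2) stats::sd(estimates) else NA_real_,
    rmse = sqrt(mean(err^2)),
    dse_full = if (!is.null(benchmark_ses))
      mean(ses) - mean(benchmark_ses) else NA_real_,
    power = 100 * mean(ci_lo > 0 | ci_hi < 0),
    coverage = 100 * mean(ci_lo <= truth & truth <= ci_hi),
    H = H)
}

#' Reporting group of a preset parameter name
#'
#' Maps parameter names to the groups used in summary reporting: `d_ar`
#' (autoregressions), `d_cr` (cross-regressions), `d_x1`/`d_x2`
#' (covariate effects), `d_var`/`d_cov` (process noise), `m_int`
#' (measurement intercepts), `m_var` (error variances), `m_load`
#' (loadings).
#'
#' @param name character vector of parameter names.
#' @return character vector of group labels.
#' @export
param_group <- function(name) {
  ifelse(grepl("^a[0-9]$", name), "d_ar",
  ifelse(grepl("^b[0-9]$", name), "d_cr",
  ifelse(grepl("^c[0-9]$", name), "d_x1",
  ifelse(grepl("^d[0-9]$", name), "d_x2",
  ifelse(grepl("^zeta_var", name), "d_var",
  ifelse(grepl("^zeta_cov", name), "d_cov",
  ifelse(grepl("^mu", name), "m_int",
  ifelse(grepl("^eps_var", name), "m_var",
  ifelse(grepl("^lambda", name), "m_load", "other")))))))))
}

#' Run all replications of one study condition
#'
#' Loops [run_replication()] over `H` replications (seed = master + h),
#' keeping the per-replication raw estimates, and aggregates them with
#' [performance_measures()]. Replications where a method failed or did not
#' converge are excluded from that method's summaries, with counts
#' reported.
#'
#' @param config a `mifs_study_config`.
#' @param benchmark fit the complete-data benchmark each replication.
#' @param progress print a line per replication.
#' @return list with `summary` (condition, method, parameter, group,
#'   truth, performance columns), `raw` (per-replication estimates),
#'   `excluded` (per-method count), and `config`.
#' @export
run_condition <- function(config, benchmark = TRUE, progress = FALSE) {
  mspec <- condition_mspec(config)
  raw <- list()
  bench_raw <- list()
  for (h in seq_len(config$H)) {
    seed <- config$master_seed + h
    rr <- run_replication(config, seed, mspec = mspec,
                          benchmark = benchmark)
    if (progress) {
      message("replication ", h, "/", config$H, " done (",
              paste(names(rr$errors), collapse = ", "),
              if (length(rr$errors)) " failed" else "", ")")
    }
    if (!is.null(rr$benchmark)) {
      bd <- tidy_result(rr$benchmark)
      bd$rep <- h
      bench_raw[[h]] <- bd
    }
    for (meth in config$methods) {
      res <- rr$results[[meth]]
      if (is.null(res)) next
      td <- tidy_result(res)
      td$method <- meth
      td$rep <- h
      raw[[length(raw) + 1L]] <- td
    }
  }
  raw <- do.call(rbind, raw)
  bench_raw <- if (length(bench_raw)) do.call(rbind, bench_raw) else NULL
  truth <- true_values(pfa_template(config$autocorr, config$null_effects))

  summ <- list()
  excluded <- stats::setNames(integer(length(config$methods)),
                              config$methods)
  for (meth in config$methods) {
    sub <- raw[raw$method == meth & raw$converged & !is.na(raw$se), ]
    reps_ok <- unique(sub$rep)
    excluded[meth] <- config$H - length(reps_ok)
    for (pn in names(truth)) {
      pr <- sub[sub$parameter == pn, ]
      if (nrow(pr) == 0) next
      bses <- if (!is.null(bench_raw)) {
        bsub <- bench_raw[bench_raw$parameter == pn &
                            bench_raw$rep %in% pr$rep, ]
        bsub$se
      } else NULL
      pm <- performance_measures(pr$estimate, pr$se, pr$ci_lo, pr$ci_hi,
                                 truth[[pn]], benchmark_ses = bses)
      summ[[length(summ) + 1L]] <- cbind(
        data.frame(autocorr = config$autocorr,
                   mechanism = config$mechanism, method = meth,
                   parameter = pn, group = param_group(pn),
                   truth = truth[[pn]]), pm)
    }
  }
  list(summary = do.call(rbind, summ), raw = raw, benchmark_raw = bench_raw,
       excluded = excluded, config = config)
}

#' Type-I error rates from a null-effects study
#'
#' For parameters whose true value is zero, the type-I rate is exactly the
#' power (percent of replications whose CI excludes zero).
#'
#' @param summary the `summary` data.frame of [run_condition()] run under
#'   `null_effects = TRUE`.
#' @return data.frame method, parameter, type1 (percent).
#' @export
typeI_rates <- function(summary) {
  sub <- summary[summary$truth == 0, ]
  if (nrow(sub) == 0) stop("no zero-valued parameters; was the study run ",
                           "with null_effects = TRUE?")
  data.frame(method = sub$method, parameter = sub$parameter,
             type1 = sub$power, row.names = NULL)
}
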