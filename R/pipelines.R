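# The four missing-data handling strategies and Rubin's-rules pooling.
#
# LD      : delete occasions with missing covariates (series re-indexed as
#           consecutive), missing indicators handled by FIML.
# MI-MV   : chained equations on manifest variables + covariates; fit each
#           completed panel; pool.
# PMI-MV  : as MI-MV, but imputed dependent-variable values are discarded
#           before fitting (FIML handles them).
# MI-FS   : factor scores estimated from the incomplete panel are added to
#           the imputation model; otherwise as MI-MV.

#' Listwise deletion pipeline
#'
#' Removes occasions with any missing covariate (remaining occasions are
#' re-indexed as consecutive, which is what alters the time dependencies),
#' keeps occasions missing only dependent variables (handled by FIML), and
#' fits the model once.
#'
#' @param panel incomplete panel.
#' @param template analysis model template.
#' @param ... passed to [fit_ml()].
#' @return a `mifs_fit` with attribute `method = "LD"`.
#' @export
run_ld <- function(panel, template, ...) {
  panel <- validate_panel(panel)
  pv <- panel_vars(panel)
  xcols <- pv$x[seq_len(template$r)]
  keep <- if (length(xcols)) rowSums(is.na(panel[xcols])) == 0 else
    rep(TRUE, nrow(panel))
  if (mean(keep) < 0.10) {
    stop("listwise deletion would retain ", sum(keep), " of ", nrow(panel),
         " occasions (< 10%); LD is not advisable here")
  }
  ld <- panel[keep, , drop = FALSE]
  ld <- ld[order(ld$id, ld$time), , drop = FALSE]
  ld$time <- stats::ave(ld$time, ld$id, FUN = seq_along)
  rownames(ld) <- NULL
  fit <- fit_ml(ld, template, ...)
  attr(fit, "method") <- "LD"
  attr(fit, "n_deleted") <- sum(!keep)
  fit
}

mi_fit_pool <- function(imputed, template, method, start = NULL,
                        reset_y_from = NULL, ...) {
  m <- length(imputed$imputations)
  sets <- lapply(imputed$imputations, function(dat) {
    if (!is.null(reset_y_from)) {
      pv <- panel_vars(dat)
      for (v in pv$y) dat[[v]][is.na(reset_y_from[[v]])] <- NA_real_
    }
    dat
  })
  # completed copies can coincide (no missing cells relevant to the fit):
  # fit each distinct dataset once so identical data give identical fits
  all_same <- m > 1 && all(vapply(sets[-1], identical, TRUE, sets[[1]]))
  fits <- vector("list", m)
  for (k in seq_len(m)) {
    if (all_same && k > 1) {
      fits[[k]] <- fits[[1]]
      next
    }
    fits[[k]] <- tryCatch(
      fit_ml(sets[[k]], template, start = start, ...),
      error = function(e) stop("imputation ", k, ": ",
                               conditionMessage(e), call. = FALSE))
    if (is.null(start)) start <- fits[[1]]$estimates
  }
  pooled <- rubin_pool(fits)
  pooled$method <- method
  pooled$rhat <- imputed$rhat
  pooled
}

#' MI with manifest variables (MI-MV)
#'
#' Chained-equations imputation of dependent variables and covariates
#' without factor scores, model fits on each completed panel, Rubin
#' pooling.
#'
#' @param panel incomplete panel.
#' @param template analysis model template.
#' @param spec imputation spec; its `include_factor_scores` flag is forced
#'   off.
#' @param imputed optional precomputed `mifs_imputed` (reused by the Monte
#'   Carlo harness); when supplied `spec` is ignored.
#' @param ... passed to [fit_ml()].
#' @return a `mifs_pooled` with `method = "MI-MV"`.
#' @export
run_mi_mv <- function(panel, template, spec = imputation_spec(),
                      imputed = NULL, ...) {
  if (is.null(imputed)) {
    spec$include_factor_scores <- FALSE
    imputed <- run_chained_equations(panel, scores = NULL, spec = spec)
  }
  mi_fit_pool(imputed, template, "MI-MV", ...)
}

#' Partial MI with manifest variables (PMI-MV)
#'
#' As MI-MV, but before each fit the dependent-variable cells that were
#' originally missing are reset to missing, so only the imputed covariates
#' are retained and the missing indicators are handled by FIML.
#'
#' @inheritParams run_mi_mv
#' @return a `mifs_pooled` with `method = "PMI-MV"`.
#' @export
run_pmi_mv <- function(panel, template, spec = imputation_spec(),
                       imputed = NULL, ...) {
  if (is.null(imputed)) {
    spec$include_factor_scores <- FALSE
    imputed <- run_chained_equations(panel, scores = NULL, spec = spec)
  }
  mi_fit_pool(imputed, template, "PMI-MV", reset_y_from = panel, ...)
}

#' MI with factor scores (MI-FS)
#'
#' Longitudinal factor scores are first estimated from the incomplete
#' panel with a covariate-free model, frozen, and added (with their lags)
#' to the chained-equations predictor set; each completed panel is then
#' fitted and the results pooled. Per-imputation fits are warm-started
#' from the factor-score-stage estimates.
#'
#' @inheritParams run_mi_mv
#' @param score_template covariate-free template for the factor-score
#'   stage (e.g. `pfa_template(covariates = FALSE)`).
#' @return a `mifs_pooled` with `method = "MI-FS"` and the score-stage fit
#'   in `$score_fit`.
#' @export
run_mi_fs <- function(panel, template, score_template,
                      spec = imputation_spec(), ...) {
  spec$include_factor_scores <- TRUE
  fs <- estimate_factor_scores(panel, score_template)
  if (!fs$fit$converged) {
    stop("factor-score stage did not converge; MI-FS aborted")
  }
  imputed <- run_chained_equations(panel, scores = fs$scores, spec = spec)
  # with nothing to impute the pipeline reduces exactly to the plain fit
  pv <- panel_vars(panel)
  warm <- if (anyNA(panel[c(pv$y, pv$x)])) fs$fit$estimates else NULL
  pooled <- mi_fit_pool(imputed, template, "MI-FS", start = warm, ...)
  pooled$score_fit <- fs$fit
  pooled
}

#' Pool repeated-imputation fits by Rubin's rules
#'
#' Pooled point \eqn{\bar Q} is the mean of the per-imputation estimates;
#' within-variance W the mean squared SE; between-variance B the sample
#' variance of the estimates; total variance \eqn{T = W + (1 + 1/m) B}.
#' Degrees of freedom use the Barnard-Rubin small-sample formula with
#' complete-data df = occasions used minus number of free parameters, and
#' confidence intervals are t-based.
#'
#' @param fits list of `mifs_fit` objects sharing a parameter set.
#' @param level confidence level (default 0.95).
#' @return object of class `mifs_pooled`: list with `table` (parameter,
#'   estimate, W, B, Tvar, se, df, ci_lo, ci_hi), `m`, `method`.
#' @export
rubin_pool <- function(fits, level = 0.95) {
  m <- length(fits)
  if (m == 0) stop("no fits to pool")
  pn <- names(fits[[1]]$estimates)
  est <- vapply(fits, function(f) f$estimates[pn], numeric(length(pn)))
  ses <- vapply(fits, function(f) f$se[pn], numeric(length(pn)))
  est <- matrix(est, nrow = length(pn))
  ses <- matrix(ses, nrow = length(pn))
  Qbar <- rowMeans(est)
  W <- rowMeans(ses^2)
  B <- if (m > 1) apply(est, 1, stats::var) else rep(0, length(pn))
  Tvar <- W + (1 + 1 / m) * B
  nu_com <- max(fits[[1]]$n_used - fits[[1]]$npar, 1)
  gamma <- ifelse(Tvar > 0, (1 + 1 / m) * B / Tvar, 0)
  nu_old <- ifelse(gamma > 0, (m - 1) / gamma^2, Inf)
  nu_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - gamma)
  df <- 1 / (1 / nu_old + 1 / nu_obs)
  se <- sqrt(Tvar)
  tq <- stats::qt(1 - (1 - level) / 2, df)
  tab <- data.frame(parameter = pn, estimate = Qbar, W = W, B = B,
                    Tvar = Tvar, se = se, df = df,
                    ci_lo = Qbar - tq * se, ci_hi = Qbar + tq * se,
                    row.names = NULL)
  structure(list(table = tab, m = m, method = NA_character_,
                 converged = all(vapply(fits, `[[`, TRUE, "converged"))),
            class = "mifs_pooled")
}

#' @export
print.mifs_pooled <- function(x, ...) {
  cat("Pooled estimates (", x$method, "), m = ", x$m, "\n", sep = "")
  print(cbind(x$table[1], round(x$table[-1], 4)))
  invisible(x)
}

# common tidy extractor used by the Monte Carlo harness
tidy_result <- function(obj) {
  if (inherits(obj, "mifs_pooled")) {
    data.frame(parameter = obj$table$parameter,
               estimate = obj$table$estimate, se = obj$table$se,
               ci_lo = obj$table$ci_lo, ci_hi = obj$table$ci_hi,
               converged = obj$converged, row.names = NULL)
  } else {
    ci <- fit_ci(obj)
    ci$converged <- obj$converged
    ci
  }
}
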