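# Logistic NMAR/MAR missingness generators.
#
# Item-dependent mechanism: each target variable v is masked with
#   P(R = 1) = logistic(phi0_v + phi1 z1 + phi2 z2 + phi3_v * v),
# evaluated on the complete value. Factor-dependent mechanism: the
# indicators of factor k share ONE Bernoulli draw per occasion with the
# latent value eta_k as the driver, so a factor's indicator block is
# always all-missing or all-observed; covariates follow the item rule in
# both mechanisms.

#' Specify a logistic missingness mechanism
#'
#' @param mechanism one of `"item_dependent"`, `"factor_dependent"`,
#'   `"mar_scattered"`, `"mar_simultaneous"`, `"composite_dependent"`.
#' @param phi0 named per-target intercepts (targets are variable names for
#'   the item rule, factor names `eta1..` for the factor rule, `"comp"`
#'   for the composite rule). Usually left `NULL` and filled by
#'   [calibrate_phi0()].
#' @param phi1,phi2 coefficients of the fully observed auxiliaries z1, z2
#'   (default 0.6 each).
#' @param phi3 named per-target driver coefficients. Defaults (the
#'   simulation preset): -0.6 for y1-y3 / eta1, +0.6 for y4-y6 / eta2,
#'   -0.8 for covariates.
#' @param target_rate intended marginal missingness proportion, in (0,1).
#' @param driver_map named list mapping each factor (or composite) to the
#'   indicator columns it drives; default the two three-indicator blocks.
#' @return object of class `mifs_missingness_spec`.
#' @export
missingness_spec <- function(mechanism = c("item_dependent",
                                           "factor_dependent",
                                           "mar_scattered",
                                           "mar_simultaneous",
                                           "composite_dependent"),
                             phi0 = NULL, phi1 = 0.6, phi2 = 0.6,
                             phi3 = NULL, target_rate = 0.3,
                             driver_map = NULL) {
  mechanism <- match.arg(mechanism)
  if (!(target_rate > 0 && target_rate < 1)) {
    stop("target_rate must be in (0, 1)")
  }
  if (is.null(driver_map)) {
    driver_map <- list(eta1 = paste0("y", 1:3), eta2 = paste0("y", 4:6))
  }
  if (is.null(phi3)) {
    phi3 <- switch(mechanism,
      item_dependent = c(y1 = -0.6, y2 = -0.6, y3 = -0.6,
                         y4 = 0.6, y5 = 0.6, y6 = 0.6,
                         x1 = -0.8, x2 = -0.8),
      factor_dependent = c(eta1 = -0.6, eta2 = 0.6,
                           x1 = -0.8, x2 = -0.8),
      composite_dependent = c(comp = -0.6, x1 = -0.8, x2 = -0.8),
      numeric(0))
  }
  structure(list(mechanism = mechanism, phi0 = phi0, phi1 = phi1,
                 phi2 = phi2, phi3 = phi3, target_rate = target_rate,
                 driver_map = driver_map),
            class = "mifs_missingness_spec")
}

logit <- function(p) log(p / (1 - p))

spec_lp <- function(spec, target, panel, driver) {
  z <- as.matrix(panel[panel_vars(panel)$z[1:2]])
  spec$phi1 * z[, 1] + spec$phi2 * z[, 2] + spec$phi3[[target]] * driver
}

need_phi0 <- function(spec, targets) {
  miss <- setdiff(targets, names(spec$phi0))
  if (length(miss)) {
    stop("phi0 not set for target(s) ", paste(miss, collapse = ", "),
         "; run calibrate_phi0() first")
  }
}

mask_with_truth <- function(panel, mask_df) {
  out <- panel
  for (v in names(mask_df)) out[[v]][mask_df[[v]]] <- NA_real_
  attr(out, "truth") <- panel
  out
}

#' Calibrate missingness intercepts to a target rate
#'
#' Solves, per target variable, for the intercept phi0 that makes the mean
#' logistic missingness probability equal `target_rate` on a large
#' reference panel, by monotone root finding. The reference panel is
#' simulated once from `params` with a fixed calibration seed, so phi0
#' does not adapt to any individual replication's noise; alternatively an
#' explicit reference `panel` (plus `latent` for the factor mechanism) can
#' be supplied.
#'
#' @param spec a `mifs_missingness_spec`.
#' @param params model used to simulate the reference panel (ignored when
#'   `panel` is given).
#' @param panel,latent optional explicit reference data.
#' @param n_persons,n_times reference panel size (default 200 x 200).
#' @param seed calibration seed (fixed default).
#' @param tol tolerance on the achieved rate.
#' @return the spec with `phi0` filled.
#' @export
calibrate_phi0 <- function(spec, params = NULL, panel = NULL, latent = NULL,
                           n_persons = 200, n_times = 200,
                           seed = 20240701L, tol = 1e-3) {
  if (is.null(panel)) {
    stopifnot(!is.null(params))
    sim <- simulate_panel(params, n_persons, n_times, seed = seed)
    panel <- sim$panel
    latent <- sim$latent
  }
  drivers <- switch(spec$mechanism,
    item_dependent = {
      tg <- names(spec$phi3)
      stats::setNames(lapply(tg, function(v) panel[[v]]), tg)
    },
    factor_dependent = {
      tg <- names(spec$phi3)
      stats::setNames(lapply(tg, function(v) {
        if (grepl("^eta", v)) latent[[v]] else panel[[v]]
      }), tg)
    },
    composite_dependent = {
      yv <- panel_vars(panel)$y
      dl <- list(comp = rowMeans(panel[yv]))
      for (v in setdiff(names(spec$phi3), "comp")) dl[[v]] <- panel[[v]]
      dl
    },
    stop("calibration applies to the logistic mechanisms only"))

  phi0 <- stats::setNames(numeric(length(drivers)), names(drivers))
  for (v in names(drivers)) {
    lp <- spec_lp(spec, v, panel, drivers[[v]])
    f <- function(b0) mean(stats::plogis(b0 + lp)) - spec$target_rate
    lo <- -30; hi <- 30
    if (f(lo) > 0 || f(hi) < 0) {
      stop("target rate ", spec$target_rate, " unreachable for ", v,
           "; achievable range [", format(mean(stats::plogis(lo + lp))),
           ", ", format(mean(stats::plogis(hi + lp))), "]")
    }
    phi0[v] <- stats::uniroot(f, c(lo, hi), tol = tol / 10)$root
  }
  spec$phi0 <- phi0
  spec
}

#' Item-dependent NMAR masking
#'
#' Masks each manifest variable and covariate independently per cell with
#' logistic probability driven by the cell's own (complete) value and the
#' auxiliaries. The pre-mask panel is kept in the `"truth"` attribute.
#'
#' @param panel complete panel with y, x, z columns.
#' @param spec calibrated `mifs_missingness_spec` (mechanism
#'   `"item_dependent"`).
#' @param seed integer seed.
#' @return the masked panel.
#' @export
apply_item_dependent <- function(panel, spec, seed = NULL) {
  panel <- validate_panel(panel)
  pv <- panel_vars(panel)
  if (length(pv$z) < 2) stop("panel must contain auxiliaries z1, z2")
  targets <- intersect(names(spec$phi3), c(pv$y, pv$x))
  need_phi0(spec, targets)
  if (!is.null(seed)) set.seed(seed)
  P <- vapply(targets, function(v) {
    stats::plogis(spec$phi0[[v]] + spec_lp(spec, v, panel, panel[[v]]))
  }, numeric(nrow(panel)))
  # one stream ordered by (person, time, variable)
  U <- matrix(stats::runif(length(P)), nrow(P), ncol(P), byrow = TRUE)
  mask <- as.data.frame(U < P)
  names(mask) <- targets
  mask_with_truth(panel, mask)
}

#' Factor-dependent NMAR masking
#'
#' For each factor, one Bernoulli draw per (person, occasion) with the
#' true latent value as driver masks all of that factor's indicators
#' simultaneously; covariates are masked by the item-dependent rule.
#'
#' @param panel complete panel.
#' @param latent true latent paths aligned with `panel` (from
#'   [simulate_panel()]).
#' @param spec calibrated spec (mechanism `"factor_dependent"`).
#' @param seed integer seed.
#' @return the masked panel (truth retained in attribute).
#' @export
apply_factor_dependent <- function(panel, latent, spec, seed = NULL) {
  panel <- validate_panel(panel)
  pv <- panel_vars(panel)
  if (length(pv$z) < 2) stop("panel must contain auxiliaries z1, z2")
  if (!identical(attr(latent, "kind"), "true")) {
    stop("latent paths must be the true trajectories (kind = 'true')")
  }
  stopifnot(nrow(latent) == nrow(panel))
  factors <- intersect(names(spec$phi3), names(spec$driver_map))
  if (!length(factors)) stop("driver map has no factor entries")
  unknown <- setdiff(factors, names(latent))
  if (length(unknown)) {
    stop("driver map references unknown factor(s): ",
         paste(unknown, collapse = ", "))
  }
  covs <- intersect(names(spec$phi3), pv$x)
  need_phi0(spec, c(factors, covs))
  if (!is.null(seed)) set.seed(seed)

  units <- c(factors, covs)
  P <- vapply(units, function(v) {
    driver <- if (v %in% factors) latent[[v]] else panel[[v]]
    stats::plogis(spec$phi0[[v]] + spec_lp(spec, v, panel, driver))
  }, numeric(nrow(panel)))
  U <- matrix(stats::runif(length(P)), nrow(P), ncol(P), byrow = TRUE)
  draw <- U < P

  mask <- list()
  for (k in seq_along(units)) {
    v <- units[k]
    if (v %in% factors) {
      for (yv in spec$driver_map[[v]]) mask[[yv]] <- draw[, k]
    } else {
      mask[[v]] <- draw[, k]
    }
  }
  mask_with_truth(panel, as.data.frame(mask))
}

#' MAR masking through random location indicators
#'
#' Draws fully observed location indicators independent of all data and
#' masks either scattered single indicators or whole factor blocks. The
#' indicators are returned so they can be used as auxiliary variables in
#' imputation.
#'
#' @param panel complete panel.
#' @param mode `"scattered"` (one indicator per y column) or
#'   `"simultaneous"` (one indicator per factor block).
#' @param rate marginal masking probability in (0,1).
#' @param seed integer seed.
#' @param driver_map factor block definition (default two blocks of 3).
#' @return list with `panel` (masked, truth retained) and `indicators`
#'   (data.frame of 0/1 location indicators, `Rloc_` prefix).
#' @export
apply_mar_location <- function(panel, mode = c("scattered", "simultaneous"),
                               rate, seed = NULL, driver_map = NULL) {
  mode <- match.arg(mode)
  if (!(rate >= 0 && rate < 1)) stop("rate must be in [0, 1)")
  panel <- validate_panel(panel)
  pv <- panel_vars(panel)
  if (is.null(driver_map)) {
    driver_map <- list(eta1 = paste0("y", 1:3), eta2 = paste0("y", 4:6))
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(panel)
  if (mode == "scattered") {
    units <- pv$y
  } else {
    units <- names(driver_map)
  }
  ind <- as.data.frame(matrix(stats::rbinom(n * length(units), 1, rate),
                              n, length(units)))
  names(ind) <- paste0("Rloc_", units)
  mask <- list()
  for (k in seq_along(units)) {
    u <- units[k]
    cols <- if (mode == "scattered") u else driver_map[[u]]
    for (yv in cols) mask[[yv]] <- ind[[k]] == 1
  }
  list(panel = mask_with_truth(panel, as.data.frame(mask)),
       indicators = ind)
}

#' Composite-driven masking for item-level VAR data
#'
#' For a panel of three observed series with no measurement model, the
#' per-occasion composite (row mean of the three series) drives one
#' Bernoulli draw per occasion that masks all three series simultaneously
#' (the misspecification scenario: missingness driven by a composite
#' "factor" when the true dynamics are at the item level). Covariates, if
#' present in the spec, follow the item rule.
#'
#' @param trivar_panel complete panel with exactly three y columns.
#' @param spec calibrated spec (mechanism `"composite_dependent"`).
#' @param seed integer seed.
#' @return the masked panel (truth retained).
#' @export
apply_composite_dependent <- function(trivar_panel, spec, seed = NULL) {
  panel <- validate_panel(trivar_panel)
  pv <- panel_vars(panel)
  if (length(pv$y) != 3) {
    stop("composite mechanism expects exactly 3 y columns, found ",
         length(pv$y))
  }
  covs <- intersect(names(spec$phi3), pv$x)
  need_phi0(spec, c("comp", covs))
  if (!is.null(seed)) set.seed(seed)
  comp <- rowMeans(panel[pv$y])
  units <- c("comp", covs)
  P <- vapply(units, function(v) {
    driver <- if (v == "comp") comp else panel[[v]]
    stats::plogis(spec$phi0[[v]] + spec_lp(spec, v, panel, driver))
  }, numeric(nrow(panel)))
  U <- matrix(stats::runif(length(P)), nrow(P), ncol(P), byrow = TRUE)
  draw <- U < P
  mask <- list()
  for (yv in pv$y) mask[[yv]] <- draw[, 1]
  for (k in seq_along(covs)) mask[[covs[k]]] <- draw[, k + 1]
  mask_with_truth(panel, as.data.frame(mask))
}

#' McKelvey-Zavoina pseudo R-squared of linear predictor terms
#'
#' Quantifies how much each term of a logistic linear predictor
#' contributes to the latent-scale variance: `share_full` is
#' Var(term) / (Var(full predictor) + pi^2/3) and `single` is the
#' single-predictor variant Var(term) / (Var(term) + pi^2/3).
#'
#' @param terms data.frame or named list of numeric vectors, each one
#'   term's contribution (coefficient times variable) to the predictor.
#' @return data.frame term, share_full, single.
#' @export
mz_rsquared <- function(terms) {
  terms <- as.data.frame(terms)
  lp <- rowSums(terms)
  denom_full <- stats::var(lp) + pi^2 / 3
  vt <- vapply(terms, stats::var, numeric(1))
  if (any(vt == 0)) warning("zero-variance predictor term; R^2 = 0")
  data.frame(term = names(terms),
             share_full = vt / denom_full,
             single = vt / (vt + pi^2 / 3),
             row.names = NULL)
}
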