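# Fully-conditional-specification (chained equations) multiple imputation
# with predictive mean matching for continuous targets and Bayesian
# logistic draws for binary targets. The imputation model can include the
# other manifest variables, covariates, frozen longitudinal factor scores,
# lag-1 (and optionally lead-1) columns, missingness indicators, and
# auxiliaries.

#' Specify a chained-equations imputation run
#'
#' @param m number of imputations (= chains).
#' @param n_iter Gibbs-style iterations per chain.
#' @param donors PMM donor pool size k.
#' @param include_factor_scores add the smoothed factor-score columns (and
#'   their lags) to the predictor pool.
#' @param include_lags,include_leads add lag-1 / lead-1 columns of every
#'   manifest, covariate and score column.
#' @param include_indicators add `R_<var>` missingness indicators (never a
#'   variable's own indicator).
#' @param include_other_manifest keep the other manifest variables in a
#'   manifest target's predictor pool (`FALSE` gives the
#'   "factor-scores-only" ablation).
#' @param methods optional named character vector overriding the
#'   per-target method (`"pmm"` or `"logistic"`); by default binary
#'   columns get logistic regression and continuous columns PMM.
#' @param maxcor collinearity guard: ordinary predictors whose absolute
#'   correlation with the target (on the observed cases, at the current
#'   working values) exceeds this are dropped from that step's model.
#'   Factor-score columns are exempt: they are the method's core
#'   auxiliary predictors, and removing them from some of a block's
#'   models while keeping them in others makes the conditionals
#'   incompatible and destabilizes the sampler (see the methods
#'   vignette).
#' @param seed integer seed; chain c uses its own substream derived from
#'   it.
#' @return object of class `mifs_imputation_spec`.
#' @export
imputation_spec <- function(m = 5, n_iter = 30, donors = 5,
                            include_factor_scores = TRUE,
                            include_lags = TRUE, include_leads = FALSE,
                            include_indicators = TRUE,
                            include_other_manifest = TRUE,
                            methods = NULL, maxcor = 0.99, seed = 1L) {
  stopifnot(m >= 1, n_iter >= 1, donors >= 1, maxcor > 0)
  structure(list(m = as.integer(m), n_iter = as.integer(n_iter),
                 donors = as.integer(donors),
                 include_factor_scores = include_factor_scores,
                 include_lags = include_lags,
                 include_leads = include_leads,
                 include_indicators = include_indicators,
                 include_other_manifest = include_other_manifest,
                 methods = methods, maxcor = maxcor,
                 seed = as.integer(seed)),
            class = "mifs_imputation_spec")
}

# first/last row index per person (panel assumed sorted)
person_bounds <- function(panel) {
  idx <- panel_index(panel)
  list(first = idx$start + 1L,
       last = idx$start + idx$len)
}

shift_lag <- function(v, first_rows, carry = FALSE) {
  out <- c(NA, v[-length(v)])
  # boundary rule: first occasion has no lag; complete (carry) columns
  # carry their own value back, incomplete ones leave NA to be imputed
  out[first_rows] <- if (carry) v[first_rows] else NA
  out
}

shift_lead <- function(v, last_rows, carry = FALSE) {
  out <- c(v[-1], NA)
  out[last_rows] <- if (carry) v[last_rows] else NA
  out
}

#' Build the augmented imputation design
#'
#' Appends, per person, lag-1 (and optionally lead-1) columns of each
#' manifest, covariate and factor-score column, `R_<var>` missingness
#' indicators (1 = missing), and the auxiliary columns. Lag/lead columns
#' of incomplete variables inherit the source's missingness (plus the
#' undefined boundary occasion) and are treated as imputation targets of
#' their own, exactly like any other incomplete variable handed to the
#' chained equations; lags of the complete factor-score columns carry the
#' boundary value back and stay complete. The default predictor matrix is
#' all-on minus self-prediction and minus any indicator identical to the
#' target's own missingness pattern.
#'
#' @param panel incomplete panel.
#' @param scores smoothed factor scores aligned with the panel (required
#'   iff `spec$include_factor_scores`).
#' @param spec a `mifs_imputation_spec`.
#' @return list with `data` (augmented data.frame), `targets` (named
#'   character vector target -> method), `predictors` (logical matrix,
#'   rows = targets, columns = predictor columns), `first`/`last` row
#'   bookkeeping and the column sets used for lag refresh.
#' @export
build_design <- function(panel, scores = NULL, spec = imputation_spec()) {
  panel <- validate_panel(panel)
  pv <- panel_vars(panel)
  if (spec$include_factor_scores && is.null(scores)) {
    stop("factor scores requested but not supplied")
  }
  pb <- person_bounds(panel)
  dat <- panel[c("id", "time", pv$y, pv$x, pv$z)]

  fs_cols <- character(0)
  if (spec$include_factor_scores) {
    stopifnot(nrow(scores) == nrow(panel))
    eta_cols <- grep("^eta[0-9]+$", names(scores), value = TRUE)
    fs_cols <- sub("^eta", "fs", eta_cols)
    for (k in seq_along(eta_cols)) dat[[fs_cols[k]]] <- scores[[eta_cols[k]]]
  }

  base_targets <- c(pv$y, pv$x)
  col_method <- function(v) {
    obs <- dat[[v]][!is.na(dat[[v]])]
    if (!is.null(spec$methods) && v %in% names(spec$methods)) {
      spec$methods[[v]]
    } else if (all(obs %in% c(0, 1))) "logistic" else "pmm"
  }

  # lag/lead columns of incomplete variables carry the source's
  # missingness (plus the undefined boundary occasion) and are imputed as
  # targets of their own, like any other variable handed to the chained
  # equations; lags of the complete score columns carry back at the
  # boundary and stay complete.
  lag_cols <- lead_cols <- shift_targets <- character(0)
  if (spec$include_lags) {
    for (v in c(pv$y, pv$x)) {
      lv <- paste0("lag_", v)
      dat[[lv]] <- shift_lag(dat[[v]], pb$first)
      lag_cols <- c(lag_cols, lv)
      shift_targets <- c(shift_targets, lv)
    }
    for (v in fs_cols) {
      lv <- paste0("lag_", v)
      dat[[lv]] <- shift_lag(dat[[v]], pb$first, carry = TRUE)
      lag_cols <- c(lag_cols, lv)
    }
  }
  if (spec$include_leads) {
    for (v in c(pv$y, pv$x)) {
      lv <- paste0("lead_", v)
      dat[[lv]] <- shift_lead(dat[[v]], pb$last)
      lead_cols <- c(lead_cols, lv)
      shift_targets <- c(shift_targets, lv)
    }
    for (v in fs_cols) {
      lv <- paste0("lead_", v)
      dat[[lv]] <- shift_lead(dat[[v]], pb$last, carry = TRUE)
      lead_cols <- c(lead_cols, lv)
    }
  }
  targets <- c(base_targets, shift_targets)
  methods <- vapply(targets, function(v) {
    col_method(sub("^(lag_|lead_)", "", v))
  }, character(1))

  ind_cols <- character(0)
  if (spec$include_indicators) {
    ind_cols <- paste0("R_", base_targets)
    for (v in base_targets) {
      dat[[paste0("R_", v)]] <- as.numeric(is.na(panel[[v]]))
    }
    # identical indicator columns (simultaneous block missingness) are
    # perfectly collinear: keep one representative per duplicate group
    keys <- vapply(ind_cols, function(ic) paste(dat[[ic]], collapse = ""),
                   character(1))
    ind_rep <- ind_cols[!duplicated(keys)]
    ind_rep <- ind_rep[vapply(ind_rep,
                              function(ic) stats::var(dat[[ic]]) > 0,
                              logical(1))]
    ind_key <- stats::setNames(keys, ind_cols)
  } else {
    ind_rep <- character(0)
  }

  pred_cols <- c(pv$y, pv$x, pv$z, fs_cols, lag_cols, lead_cols, ind_rep)
  P <- matrix(TRUE, length(targets), length(pred_cols),
              dimnames = list(targets, pred_cols))
  for (v in targets) {
    P[v, v] <- FALSE                       # no self-prediction
    if (length(ind_rep)) {
      # a target never sees an indicator identical to its own missingness
      # pattern (self-masking degeneracy)
      vkey <- paste(as.numeric(is.na(dat[[v]])), collapse = "")
      same <- ind_rep[ind_key[ind_rep] == vkey]
      P[v, same] <- FALSE
    }
    if (!spec$include_other_manifest) {
      src <- sub("^(lag_|lead_)", "", v)
      if (src %in% pv$y) {
        others <- setdiff(pv$y, src)
        P[v, intersect(others, pred_cols)] <- FALSE
        P[v, intersect(paste0("lag_", others), pred_cols)] <- FALSE
        P[v, intersect(paste0("lead_", others), pred_cols)] <- FALSE
      }
    }
  }

  list(data = dat, targets = methods, predictors = P,
       y_cols = pv$y, x_cols = pv$x, shift_targets = shift_targets,
       first = pb$first, last = pb$last)
}

# Bayesian linear regression draw + donor matching (type-1 PMM):
# predictions for observed cases use the posterior mode, predictions for
# missing cases a posterior draw; each missing case receives the observed
# value of one of the k donors with closest predicted mean.

#' Predictive mean matching imputation step
#'
#' @param target numeric vector with `NA` at the cells to impute.
#' @param predictors complete numeric matrix/data.frame of predictors.
#' @param donors donor pool size k.
#' @return numeric vector of imputed values for the missing cells, each an
#'   observed value of `target`.
#' @export
pmm_step <- function(target, predictors, donors = 5) {
  X <- cbind(`(Intercept)` = 1, as.matrix(predictors))
  obs <- !is.na(target)
  nobs <- sum(obs)
  if (nobs == 0) stop("no observed cases to match against")
  k <- donors
  if (nobs < k + 2) {
    k <- max(1L, nobs - 2L)
    warning("donor pool reduced to ", k, " (few observed cases)")
  }
  Xo <- X[obs, , drop = FALSE]
  yo <- target[obs]
  XtX <- crossprod(Xo)
  d <- ncol(X)
  V <- tryCatch(chol2inv(chol(XtX)), error = function(e) NULL)
  if (is.null(V)) {
    warning("singular imputation design; ridge fallback")
    V <- chol2inv(chol(XtX + diag(1e-5 * (diag(XtX) + 1), d)))
  }
  beta_hat <- V %*% crossprod(Xo, yo)
  res <- yo - Xo %*% beta_hat
  df <- max(nobs - d, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  Lv <- tryCatch(t(chol(V)), error = function(e) {
    ev <- eigen(0.5 * (V + t(V)), symmetric = TRUE)
    ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), d)
  })
  beta_star <- beta_hat + Lv %*% stats::rnorm(d) * sqrt(sigma2)
  yhat_obs <- as.numeric(Xo %*% beta_hat)
  yhat_mis <- as.numeric(X[!obs, , drop = FALSE] %*% beta_star)

  # the k nearest donors in the sorted prediction array form a contiguous
  # window: start from a 2k window around the insertion point and shrink
  # it from whichever end is farther (vectorized over missing cells)
  ord <- order(yhat_obs)
  ys <- yhat_obs[ord]
  yo_s <- yo[ord]
  n_mis <- length(yhat_mis)
  pos <- findInterval(yhat_mis, ys)
  lo <- pmin(pmax(pos - k + 1L, 1L), nobs - k + 1L)
  hi <- pmax(pmin(pos + k, nobs), k)
  w <- hi - lo + 1L
  while (any(w > k)) {
    sh <- w > k
    drop_lo <- sh & (yhat_mis - ys[lo] > ys[hi] - yhat_mis)
    lo[drop_lo] <- lo[drop_lo] + 1L
    keep_hi <- sh & !drop_lo
    hi[keep_hi] <- hi[keep_hi] - 1L
    w <- hi - lo + 1L
  }
  yo_s[lo + sample.int(k, n_mis, replace = TRUE) - 1L]
}

# penalized IRLS used as the separation / rank-deficiency fallback
ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 50) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    A <- crossprod(X * w, X) + diag(lambda, ncol(X))
    beta_new <- solve(A, crossprod(X * w, z))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  list(beta = as.numeric(beta), vcov = solve(A))
}

#' Bayesian logistic imputation step for a binary target
#'
#' ML logistic fit on the observed cases, an approximate posterior draw of
#' the coefficients (normal around the MLE with covariance the inverse
#' observed information), and a Bernoulli draw per missing case. Complete
#' separation or rank deficiency triggers a ridge-penalized fit; a single
#' observed class is imputed deterministically.
#'
#' @inheritParams pmm_step
#' @return 0/1 vector of imputed values for the missing cells.
#' @export
logistic_step <- function(target, predictors) {
  X <- cbind(`(Intercept)` = 1, as.matrix(predictors))
  obs <- !is.na(target)
  yo <- target[obs]
  Xo <- X[obs, , drop = FALSE]
  Xm <- X[!obs, , drop = FALSE]
  n_mis <- nrow(Xm)
  classes <- unique(yo)
  if (length(classes) < 2) {
    warning("single observed class; imputing it deterministically")
    return(rep(classes, n_mis))
  }
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(Xo, yo, family = stats::binomial())),
    error = function(e) NULL)
  ok <- !is.null(fit) && fit$converged && fit$rank == ncol(Xo) &&
    max(abs(fit$coefficients)) < 15
  if (ok) {
    Rq <- qr.R(fit$qr)
    V <- tryCatch(chol2inv(Rq), error = function(e) NULL)
    beta_hat <- fit$coefficients
    ok <- !is.null(V)
  }
  if (!ok) {
    warning("logistic fit unstable (separation or rank deficiency); ",
            "ridge fallback")
    rf <- ridge_logistic(Xo, yo)
    beta_hat <- rf$beta
    V <- rf$vcov
  }
  L <- tryCatch(t(chol(V)), error = function(e) diag(0, ncol(Xo)))
  beta_star <- beta_hat + as.numeric(L %*% stats::rnorm(ncol(Xo)))
  p <- stats::plogis(as.numeric(Xm %*% beta_star))
  stats::rbinom(n_mis, 1, p)
}

#' Run chained-equations multiple imputation
#'
#' Per chain: missing cells are initialized by draws from each column's
#' observed values; each iteration visits all manifest targets in column
#' order, then all covariate targets, then the lag/lead targets,
#' refitting the univariate model on the originally observed cases
#' conditional on current working values and redrawing the missing cells.
#' After `n_iter` iterations the working y and x columns form that
#' chain's completed copy (imputed lag columns are internal to the
#' imputation model and discarded).
#'
#' @param panel incomplete panel.
#' @param scores optional smoothed factor scores (see [build_design()]).
#' @param spec a `mifs_imputation_spec`.
#' @return object of class `mifs_imputed`: list with `imputations` (m
#'   completed panels), `traces` (chain, iteration, variable, mean, sd of
#'   imputed values), `rhat` (per-variable potential scale reduction on
#'   chain means, second half of iterations), and `spec`.
#' @export
run_chained_equations <- function(panel, scores = NULL,
                                  spec = imputation_spec()) {
  design <- build_design(panel, scores, spec)
  dat0 <- design$data
  targets <- names(design$targets)
  miss <- lapply(targets, function(v) which(is.na(dat0[[v]])))
  names(miss) <- targets
  active <- targets[vapply(miss, length, 1L) > 0]

  imputations <- vector("list", spec$m)
  # nothing to impute in the panel itself (boundary lag cells alone do
  # not affect the completed copies): the engine is the identity
  if (!any(c(design$y_cols, design$x_cols) %in% active)) active <- character(0)
  if (length(active) == 0) {
    for (c in seq_len(spec$m)) imputations[[c]] <- panel
    return(structure(list(imputations = imputations,
                          traces = data.frame(), rhat = numeric(0),
                          spec = spec), class = "mifs_imputed"))
  }

  visit <- c(intersect(design$y_cols, active),
             intersect(design$x_cols, active),
             intersect(design$shift_targets, active))
  all_cols <- colnames(design$predictors)
  work_cols <- union(all_cols, targets)
  M0 <- as.matrix(dat0[work_cols])      # all-numeric working matrix
  pred_idx <- lapply(targets, function(v) {
    match(all_cols[design$predictors[v, ]], work_cols)
  })
  names(pred_idx) <- targets
  tgt_idx <- match(targets, work_cols)
  names(tgt_idx) <- targets

  n_tr <- spec$m * spec$n_iter * length(visit)
  tr_mean <- tr_sd <- numeric(n_tr)
  tr_chain <- tr_iter <- tr_n <- integer(n_tr)
  tr_var <- character(n_tr)
  tr_k <- 0L

  for (chain in seq_len(spec$m)) {
    set.seed(spec$seed + 7919L * chain)
    M <- M0
    for (v in active) {
      col <- tgt_idx[[v]]
      pool <- M[, col][!is.na(M[, col])]
      M[miss[[v]], col] <- sample(pool, length(miss[[v]]), replace = TRUE)
    }
    for (iter in seq_len(spec$n_iter)) {
      for (v in visit) {
        col <- tgt_idx[[v]]
        tgt <- M0[, col]          # NA exactly at originally missing cells
        ok_rows <- !is.na(tgt)
        P <- M[, pred_idx[[v]], drop = FALSE]
        # collinearity guard (as in standard FCS implementations): drop
        # constant predictors and those nearly interpolating the target.
        # Factor-score columns are exempt — dropping a score from part of
        # an indicator block's models leaves incompatible conditionals
        # and destabilizes the sampler.
        cors <- suppressWarnings(
          stats::cor(tgt[ok_rows], P[ok_rows, , drop = FALSE]))
        is_score <- grepl("^(lag_|lead_)?fs[0-9]+$", colnames(P))
        keep <- is.finite(cors) &
          (is_score | abs(cors) <= spec$maxcor)
        P <- P[, keep, drop = FALSE]
        imp <- withCallingHandlers(
          if (design$targets[[v]] == "logistic") {
            logistic_step(tgt, P)
          } else {
            pmm_step(tgt, P, donors = spec$donors)
          },
          warning = function(w) {
            warning(sprintf("chain %d, iteration %d, variable %s: %s",
                            chain, iter, v, conditionMessage(w)),
                    call. = FALSE)
            invokeRestart("muffleWarning")
          })
        M[miss[[v]], col] <- imp
        tr_k <- tr_k + 1L
        tr_chain[tr_k] <- chain; tr_iter[tr_k] <- iter; tr_var[tr_k] <- v
        tr_mean[tr_k] <- mean(imp); tr_sd[tr_k] <- stats::sd(imp)
        tr_n[tr_k] <- length(imp)
      }
    }
    completed <- panel
    for (v in c(design$y_cols, design$x_cols)) {
      completed[[v]] <- M[, tgt_idx[[v]]]
    }
    attr(completed, "truth") <- NULL
    imputations[[chain]] <- completed
  }

  traces <- data.frame(chain = tr_chain[seq_len(tr_k)],
                       iteration = tr_iter[seq_len(tr_k)],
                       variable = tr_var[seq_len(tr_k)],
                       mean = tr_mean[seq_len(tr_k)],
                       sd = tr_sd[seq_len(tr_k)],
                       n = tr_n[seq_len(tr_k)])
  structure(list(imputations = imputations, traces = traces,
                 rhat = rhat(traces), spec = spec),
            class = "mifs_imputed")
}

#' Gelman-Rubin potential scale reduction of imputation chains
#'
#' Compares within-chain variance to the variance of the pooled draws
#' across chains, per imputed variable. Two conventions are provided:
#'
#' * `type = "draws"` (default): the draws are the imputed values
#'   themselves. Within-chain variance is the total variance of a chain's
#'   imputed values over the retained iterations (recovered from the
#'   mean/sd traces by the law of total variance) and the between
#'   component is the spread of the chains' grand means, so
#'   \eqn{\hat R = \sqrt{(n-1)/n + \mathrm{Var}_c(\bar y_c)/W}} with n
#'   the number of retained draws per chain. Chains imputing in different
#'   regions of the variable's scale are flagged; small chain offsets
#'   relative to the imputation spread are not.
#' * `type = "means"`: the classical statistic applied to the
#'   per-iteration chain means of imputed values. Far more sensitive: when
#'   imputations are tightly pinned (e.g. by factor-score predictors) the
#'   mean series has almost no within-chain variance and minute chain
#'   offsets produce large values (see the methods vignette).
#'
#' @param traces data.frame with columns chain, iteration, variable,
#'   mean, sd, n (as produced by [run_chained_equations()]).
#' @param keep_frac fraction of final iterations retained (default 1).
#' @param type `"draws"` or `"means"` (see above).
#' @return named numeric vector of statistics; variables with zero
#'   within-chain variance are reported as 1 with attribute
#'   `zero_within`.
#' @export
rhat <- function(traces, keep_frac = 1, type = c("draws", "means")) {
  type <- match.arg(type)
  if (NROW(traces) == 0) return(numeric(0))
  vars <- unique(traces$variable)
  n_iter <- max(traces$iteration)
  keep <- traces$iteration > floor(n_iter * (1 - keep_frac))
  tr <- traces[keep, ]
  zero_flag <- character(0)
  out <- vapply(vars, function(v) {
    tv <- tr[tr$variable == v, ]
    M <- tapply(tv$mean, list(tv$iteration, tv$chain), identity)
    n_it <- nrow(M); m <- ncol(M)
    if (is.null(n_it) || n_it < 2 || m < 2) return(NA_real_)
    if (type == "means") {
      W <- mean(apply(M, 2, stats::var))
      B <- n_it * stats::var(colMeans(M))
      if (W == 0) {
        zero_flag <<- c(zero_flag, v)
        return(1)
      }
      return(sqrt(((n_it - 1) / n_it * W + B / n_it) / W))
    }
    S <- tapply(tv$sd, list(tv$iteration, tv$chain), identity)
    S[is.na(S)] <- 0            # single-cell iterations have no spread
    n_cells <- tv$n[1]
    # within-chain draw variance by the law of total variance
    W_c <- colMeans(S^2, na.rm = TRUE) +
      apply(M, 2, stats::var) * (n_it - 1) / n_it
    W <- mean(W_c)
    if (W == 0) {
      zero_flag <<- c(zero_flag, v)
      return(1)
    }
    n <- n_it * n_cells
    sqrt((n - 1) / n + stats::var(colMeans(M)) / W)
  }, numeric(1))
  names(out) <- vars
  if (length(zero_flag)) attr(out, "zero_within") <- zero_flag
  out
}
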