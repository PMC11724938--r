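---
title: "Factor-score multiple imputation for intensive longitudinal data: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factor-score multiple imputation for intensive longitudinal data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ecological momentary assessments and other intensive longitudinal designs
measure latent constructs (affect, stress) through multiple items, many
times per person. When the *latent* construct drives nonresponse — a
highly stressed participant skips the whole stress scale — every indicator
of that factor goes missing at once. This is nonignorable (NMAR)
missingness with a simultaneous, block-wise pattern: at the affected
occasions there are no sibling items left to inform an imputation model,
which defeats the usual chained-equations setup.

`mifs` implements and evaluates a pragmatic remedy: estimate longitudinal
factor scores from the incomplete panel with a state-space factor model,
freeze them, and hand them to a chained-equations imputation as auxiliary
predictors alongside lagged variables and missingness indicators (the
MI-FS strategy). The package contains everything needed to study the
approach end to end: the data-generating process, the missingness
generators, the estimation machinery, four missing-data handling
pipelines, Rubin pooling, and a Monte Carlo harness.

## Model

The core is the linear Gaussian state-space form of a process factor
analysis (PFA) model,

$$\eta_{i,t} = \alpha + F\,\eta_{i,t-1} + B\,x_{i,t} + \zeta_{i,t},
  \qquad \zeta_{i,t}\sim N(0,\Sigma_\zeta),$$
$$y_{i,t} = \tau + \Lambda\,\eta_{i,t} + A\,x_{i,t} + \epsilon_{i,t},
  \qquad \epsilon_{i,t}\sim N(0,\Sigma_\epsilon),$$

with $q$ latent factors following a VAR(1) with covariate effects, and $p$
manifest indicators. The simulation preset (`pfa_template()`) is a
bivariate process measured by six indicators (three per factor, anchor
loadings fixed at 1 for identification), with a binary and a continuous
time-varying covariate entering the dynamic model:
AR coefficients 0.5 (low) or 0.7 (high autocorrelation), cross-regressions
$-0.2$ and $-0.3$, covariate effects $(0.3, -0.3, 0.5, -0.4)$, process
noise covariance $[2, 0.5; 0.5, 6]$, intercepts 3, free loadings
$(2, 1, 2, 1)$ and unit error variances. The second factor has three times
the process noise of the first, which is why its parameters are
consistently the harder ones to recover.

Estimation maximizes the prediction-error-decomposition likelihood: the
Kalman filter turns the panel into one-step prediction errors and their
covariances, using only the observed indicator rows at each occasion
(full-information ML), and a quasi-Newton optimizer (BFGS, numerical
gradients, up to 3 jittered restarts) works on transformed parameters —
log variances, log-Cholesky process noise covariance. Standard errors come
from the inverse of a forward-difference Hessian computed on the natural
scale. The fixed-interval (Rauch–Tung–Striebel) smoother then yields
factor scores $E[\eta_{i,t}\mid y_{i,1..T_i}]$ defined at every occasion,
including fully missing ones. With a null transition matrix the smoother
reduces to the classical regression factor-score estimator, which the test
suite verifies to $10^{-8}$.

### Initial condition and stability

The generating model and the estimator both need a distribution for the
first occasion. The package uses the stationary solution implied by the
current parameters, with the covariate contribution $B\,S_x B'$ (empirical
covariate moments) added to the Lyapunov constant so the initial
distribution matches the generating process. A consequence worth stating:
during optimization the stationary solve fails for unstable transition
matrices, so the likelihood itself confines the search to the stable
region; an explicitly unstable simulation is still possible by supplying
`init_mean`/`init_cov` and `allow_unstable = TRUE`. Burn-in is available
(`burn_in` argument) but unnecessary under the stationary start, and 0 by
default.

### Missing covariates in the likelihood

The filter handles missing indicators row-wise, but the state equation
needs the covariates at every occasion. Occasions with a missing covariate
are excluded from the likelihood (their indicator rows are treated as
missing, and counted in `n_excluded`); for the state propagation only, the
missing covariate value is replaced by its observed column mean. In the
shipped pipelines this path is rarely exercised: listwise deletion removes
such rows beforehand, the MI pipelines impute them, and the factor-score
stage uses a covariate-free model.

## Missingness generators

Two logistic NMAR mechanisms mirror the study conditions, both calibrated
to a 30% marginal rate per variable:

* **item-dependent** — each manifest variable and covariate is masked
  independently per cell with probability
  $\mathrm{logit}^{-1}(\phi_0 + 0.6 z_1 + 0.6 z_2 + \phi_3 v)$, driven by
  its own (complete) value; $\phi_3$ is $-0.6$ for the first factor's
  indicators, $+0.6$ for the second factor's, $-0.8$ for covariates.
* **factor-dependent** — one Bernoulli draw per (person, occasion, factor)
  with the true latent value as driver masks the factor's whole indicator
  block, so the block is always all-missing or all-observed; covariates
  keep the item rule.

The auxiliaries $z_1, z_2 \sim U(-3,3)$ are fully observed. The covariate
distributions are not pinned down by the study conditions; the package
uses $x_1\sim\mathrm{Bernoulli}(0.5)$ and $x_2\sim N(0,1)$, i.i.d. across
persons and occasions — a minimal binary + continuous pair, and the binary
driver enters the logistic predictor as 0/1. Intercepts $\phi_0$ are
calibrated by monotone root finding of the mean logistic probability on a
dedicated 200×200 reference panel simulated with a fixed calibration seed,
so the intercepts never adapt to an individual replication's noise;
out-of-sample the achieved rates sit within ±0.02 of the target. MAR
location-indicator variants (scattered/simultaneous) and the
composite-driven tri-VAR misspecification scenario are provided for
sensitivity analyses. McKelvey–Zavoina pseudo-$R^2$ contributions of the
predictor terms are computed in both conventions on offer (variance share
of the full predictor, and single-predictor), since the convention is a
genuine degree of freedom.

## Chained-equations imputation

The engine is a fully conditional specification sampler: per chain,
missing cells start as draws from the observed margins; each iteration
revisits every incomplete variable, refits its univariate model on the
originally observed cases given current working values, and redraws the
missing cells. Continuous targets use predictive mean matching (Bayesian
linear regression draw, donor pool of the $k=5$ observed cases with
closest predicted mean, type-1 matching: posterior-mode predictions for
donors, posterior-draw predictions for recipients), binary targets a
Bayesian logistic draw. $k=5$ follows common default practice. The
predictor pool holds the other manifest variables, the covariates, the
auxiliaries, the frozen smoothed factor scores, lag-1 columns of the
manifest, covariate and score columns, and the missingness indicators
(never one whose pattern coincides with the target's own missingness).

Three design points deserve explanation because they were learned the hard
way, from the behaviour of the sampler on the factor-dependent condition:

* **Lags are imputed, not recomputed.** Lag columns of incomplete
  variables inherit the source's (shifted) missingness plus the undefined
  first occasion, and are treated as imputation targets of their own —
  exactly what happens when lagged variables are passed to a standard
  chained-equations package, which has no notion of a derived column.
  The alternative — deterministically refreshing lags from working values
  each iteration — couples the chain state so tightly that each chain
  freezes at its own fixed point (between-chain $\hat R$ of 5–7). Imputed
  lag columns are internal to the imputation model and are discarded from
  the completed panels.
* **A collinearity guard is essential with factor scores.** A smoothed
  score is a near-linear combination of the observed indicators, and for a
  high-loading indicator the score predicts it almost perfectly
  (correlations 0.986–0.994 in the study conditions, regression
  $R^2 > 0.999$). Donor selection then degenerates and the chain stops
  moving. Each univariate step therefore drops constant predictors and
  ordinary predictors whose absolute correlation with the target (on
  observed cases, at current working values) exceeds 0.99, the default
  guard of standard FCS implementations. The factor-score columns are
  *exempt* from this guard. The score of a high-loading indicator sits
  right at the guard boundary (correlations 0.986–0.994 in the study
  conditions), and removing it from that one indicator's model while the
  block-mates keep theirs leaves the block with incompatible
  conditionals: the guarded indicator is then predicted only through its
  (imputed) block-mates, a feedback loop whose predictive distribution
  degenerates — imputed spreads three times the marginal SD and Heywood
  solutions in the downstream fits. With the scores kept everywhere the
  sampler is stable; the price is the tight pinning of imputed
  high-loading indicators to their score-implied values, which is the
  very mechanism behind the documented loss of item-level variability
  under factor-score imputation.
* **Convergence is monitored on the imputed draws.** $\hat R$ compares
  within-chain variance to the variance of the pooled draws across
  chains, per variable. The default (`type = "draws"`) takes the draws to
  be the imputed values themselves, so the between-chain component is
  judged relative to the imputation spread; with $m=5$ chains and 30
  iterations the study condition stays at $\max \hat R$ comfortably
  below 1.1. The classical statistic on the *per-iteration chain means*
  (`type = "means"`) is also provided, and users should understand why it
  behaves differently here: when a high-loading indicator's imputations
  are pinned by its factor score, the mean series has almost no
  within-chain variance, and chain-level offsets that are negligible on
  the variable's scale (well under a tenth of its SD) blow the statistic
  up to 1.4–2. That variant flags *any* persistent offset, however small;
  the draws variant flags offsets that matter relative to the imputation
  distribution. Both are computed over the full chain series by default
  (`keep_frac` restricts to the tail).

Reproducibility: each chain derives its own seed from the spec seed, so
`m` chains are independent streams and reruns are bit-identical.

## The four pipelines

* **LD** deletes occasions with missing covariates and re-indexes the
  remaining occasions as consecutive — precisely the distortion of time
  dependencies that makes listwise deletion biased in dynamic models;
  occasions missing only indicators stay and are handled by the filter.
* **MI-MV** imputes manifest variables and covariates without factor
  scores, fits each completed panel, and pools.
* **PMI-MV** runs the same imputation but discards the imputed indicator
  values before fitting (covariates retained; indicators handled by
  full-information ML).
* **MI-FS** estimates factor scores from the incomplete panel with the
  covariate-free model, aborts loudly if that stage does not converge,
  imputes with the scores in the pool, fits and pools. Per-imputation fits
  are warm-started from the score-stage estimates (a pure optimization
  shortcut; with nothing to impute the pipeline reduces exactly to the
  plain fit).

Pooling follows Rubin's rules: $\bar Q$, within-variance $W$,
between-variance $B$, $T = W + (1+1/m)B$; degrees of freedom use the
Barnard–Rubin small-sample formula with complete-data df equal to the
number of occasions used minus the number of free parameters, and CIs are
$t$-based. Single-fit methods use normal-quantile CIs. "Significant" for
power means the CI excludes 0. The df formula and CI type are not uniquely
determined by the study design; Barnard–Rubin is the standard small-sample
choice and is flagged here as a sensitivity point.

## Monte Carlo harness

`run_condition()` crosses autocorrelation (0.5 / 0.7) with mechanism
(item / factor dependent), runs H replications of
simulate → benchmark fit → mask → handle → fit → pool, and summarizes
bias, relative bias, mean SE, MCSE, RMSE, dSEfull (mean SE minus the
complete-data benchmark's mean SE), power and coverage per parameter, with
parameters also grouped (d_ar, d_cr, d_x1, d_x2, d_var, d_cov, m_int,
m_var, m_load). Replication h uses seed master+h; all methods in a
replication consume the same masked panel (paired design), and MI-MV and
PMI-MV share one chained-equations run since their imputation models are
identical. Nonconvergent or failed method runs are excluded from summaries
with reported counts. A `null_effects` flag zeroes the cross-regression
and covariate coefficients for type-I-error studies, where the type-I rate
of a zero-true parameter is exactly its power.

### Problem sizes used by the shipped checks

The full design (500 replications × 4 conditions × 4 methods) is a
cluster-scale computation. The package's own test suite exercises the same
machinery at sizes chosen to keep a complete run on a single CPU within a
coffee break: the factor-score-recovery and imputation-convergence checks
run at the study's native 30×100 panel size; the comparative RMSE/coverage
checks run the native panel size at H = 3 replications per condition
(low autocorrelation with MI-FS; high autocorrelation with LD and
MI-MV) — enough to pin down the large documented effects
(binary-covariate coefficient RMSEs near 0.1, severe undercoverage of
loadings and variance parameters under MI-FS) while acknowledging that
two-digit agreement with full-design numbers is not attainable at this H;
and the complete-data CI-validity check runs H = 100 single fits.
`run_study()` exposes presets (`smoke = 2`, `scaled = 50`, `full = 500`)
for users who want the full picture.

## What the generator does and does not emulate

The synthetic data are exactly the stated study conditions: stationary
bivariate VAR(1) dynamics, time-invariant parameters, homogeneous persons,
equally spaced occasions, diagonal measurement error, i.i.d. covariates,
uniform auxiliaries, and logistic missingness driven by items or factors.
Real EMA data violate most of these in some degree — person-specific
baselines and dynamics, unequal spacing, correlated measurement errors,
drifting missingness rates. Passing tests therefore demonstrate that the
algorithms are implemented correctly and behave as documented *under the
stated conditions*, not that MI-FS is safe on any particular empirical
dataset; the misspecification scenario (composite-driven tri-VAR) is the
package's built-in probe for the most consequential violation, a wrong
factor structure.

## Numerical choices and degenerate inputs

Innovation covariances are Cholesky-factorized with symmetrization; a
non-PD innovation covariance makes the likelihood infinite, which the
optimizer treats as a barrier. Filter/smoother covariances are asserted
PSD to $-10^{-10}$ in the property tests. PMM reduces its donor count with
a warning when fewer than $k+2$ observed cases exist, and falls back to a
ridge ($10^{-5}$) on singular designs; the logistic step falls back to a
ridge-penalized IRLS under separation or rank deficiency and imputes
deterministically when only one class is observed. Zero within-chain
variance reports $\hat R = 1$ with a flag. Listwise deletion refuses to
proceed (error, not warning) when fewer than 10% of occasions survive.

## Known limitations

* Slow FCS mixing for high-loading indicators under factor-score
  imputation (see above) — the draws-based $\hat R$ judges the resulting
  chain offsets negligible; the iteration-means variant flags them.
* Measurement intercepts under high autocorrelation behave differently
  here than in workflows without a stability constraint. Predictive mean
  matching cannot generate values outside the observed support, and at a
  masked block the block-mates dominate the predictive model, diluting
  the lagged information; the resulting truncation bias shifts the
  imputed blocks toward the observed center (upward for the
  low-missing-at-high tail, downward for the opposite one) and grows with
  the latent variance, so MI intercept RMSEs at AR = 0.7 are
  substantially larger than at AR = 0.5. Listwise deletion, by contrast,
  deletes at random with respect to the indicators and — with the
  stationary-initial-condition likelihood keeping fits inside the stable
  region — recovers intercepts comparatively well here, without the
  intercept blowups near the unit root that penalize it elsewhere.
* The factor-score stage ignores covariate effects by construction, so its
  dynamic-parameter estimates are biased; the scores remain useful as
  imputation predictors but MI-FS inherits a documented tendency to
  underestimate process noise variances and their SEs, and to undercover
  loadings and variance parameters.
* Only diagonal measurement error covariance is estimable; multilevel
  (random-effect) extensions, continuous-time dynamics, and
  model-compatible (Bartlett) imputation are out of scope.
* The Barnard–Rubin df and t-CIs are a convention choice; with m = 5 and
  mild fractions of missing information the practical impact is small.
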