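# mifs — multiple imputation with longitudinal factor scores

Intensive longitudinal studies (e.g. ecological momentary assessment)
measure latent constructs through multiple items, many times per person.
When the latent construct itself drives nonresponse — a stressed
participant skips the whole stress scale — all indicators of that factor
go missing simultaneously, a nonignorable (NMAR) pattern that standard
imputation handles poorly because the most informative sibling items are
missing at exactly the occasions that need them.

`mifs` implements the **MI-FS** strategy for this setting, together with
the machinery to evaluate it:

* a linear Gaussian state-space / process factor analysis (PFA) core:
  simulation, Kalman filtering, fixed-interval smoothing, and maximum
  likelihood by prediction error decomposition (compiled recursions via
  RcppArmadillo),
* logistic NMAR/MAR missingness generators (item-dependent,
  factor-dependent, location-indicator MAR, composite-driven), calibrated
  to a target rate,
* a chained-equations multiple imputation engine (predictive mean
  matching for continuous targets, Bayesian logistic draws for binary
  ones) whose predictor pool includes smoothed factor scores, lagged
  variables, missingness indicators and auxiliaries,
* four missing-data handling pipelines — listwise deletion (LD), MI on
  manifest variables (MI-MV), partial MI (PMI-MV, imputed indicators
  discarded and handled by FIML), and MI with factor scores (MI-FS) —
  with Rubin's-rules pooling (Barnard–Rubin df),
* a Monte Carlo harness reporting bias, relative bias, SE, MCSE, RMSE,
  dSEfull, power and coverage per parameter and parameter group.

The analysis model is
η<sub>t</sub> = α + F η<sub>t−1</sub> + B x<sub>t</sub> + ζ<sub>t</sub>,
y<sub>t</sub> = τ + Λ η<sub>t</sub> + A x<sub>t</sub> + ε<sub>t</sub>,
a bivariate VAR(1) latent process measured by six indicators in the
shipped preset. See `vignettes/mifs-methods.Rmd` for the model,
algorithms, tuning parameters and design decisions.

## Worked example

```r
library(mifs)

template       <- pfa_template("low")                      # AR = 0.5 preset
score_template <- pfa_template("low", covariates = FALSE)

sim    <- simulate_panel(template, n_persons = 30, n_times = 100, seed = 3)
mspec  <- calibrate_phi0(missingness_spec("factor_dependent"), params = template)
masked <- apply_factor_dependent(sim$panel, sim$latent, mspec, seed = 4)
round(missingness_summary(masked)$rates, 2)
#>   y1   y2   y3   y4   y5   y6   x1   x2
#> 0.32 0.32 0.32 0.31 0.31 0.31 0.30 0.30

fit <- run_mi_fs(masked, template, score_template,
                 spec = imputation_spec(m = 5, n_iter = 30, seed = 9))
max(fit$rhat)                       # chained-equations convergence
#> [1] 1.0013
subset(fit$table, parameter %in% c("a1", "b1", "c1"))
#>   parameter estimate        W        B     Tvar     se  df   ci_lo  ci_hi
#> 1        a1    0.575 0.000221 1.23e-05 0.000236 0.0154 748  0.5451  0.605
#> 3        b1   -0.197 0.000139 9.14e-06 0.000150 0.0122 586 -0.2210 -0.173
#> 5        c1    0.138 0.002278 3.96e-04 0.002753 0.0525 127  0.0343  0.242
```

Each per-variable missingness rate lands near the calibrated 30% target.
The pooled cross-regression `b1` recovers its generating value (−0.2)
almost exactly; the autoregression `a1` (true 0.5) is pulled upward and
the binary-covariate effect `c1` (true 0.3) attenuated — the documented
behaviour of factor-score imputation under factor-driven nonresponse on a
single replication. Confidence intervals are t-based with total variance
combining within- (`W`) and between-imputation (`B`) uncertainty. The
`fit$rhat` diagnostic is the Gelman–Rubin statistic across the five
imputation chains; values at or below 1.1 indicate the chains mixed.

A scaled-down Monte Carlo comparison of all four pipelines:

```r
cfg <- study_config("low", "factor_dependent",
                    methods = c("LD", "MI-MV", "PMI-MV", "MI-FS"),
                    H = 2, master_seed = 1)   # smoke preset; scaled = 50
out <- run_study(cfg, out_dir = "mifs_results")
subset(out$summary, parameter == "a1",
       select = c(method, bias, rmse, coverage))
```

A thin command-line wrapper over the same functions ships in
`inst/cli/mifs.R` (subcommands `simulate`, `mask`, `study`).

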