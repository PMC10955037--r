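# bcfselect

Individualised treatment selection between two glucose-lowering drug
classes — SGLT2 inhibitors (SGLT2i) and GLP-1 receptor agonists (GLP1-RA) —
for people with type 2 diabetes, from routine clinical features. The package
is aimed at biostatisticians and pharmacoepidemiologists who want to build,
probe or extend outcome-based treatment selection models on observational
cohorts where treatment is assigned by indication and individual
counterfactuals are unobservable.

At its core is a from-scratch **Bayesian causal forest** fitted by
backfitting MCMC (Rcpp). With `z = 1` coding GLP1-RA,

    y_i = mu(x_i) + tau(x_i) * z_i + e_i,   e_i ~ N(0, sigma^2)

where `mu` is a prognostic sum-of-trees ensemble (depth prior
`0.95 (1+d)^-2`) and `tau` a smaller, shallower treatment-effect ensemble
(`0.25 (1+d)^-3`) whose leaf scale carries a half-normal hyperprior, so the
effect surface is shrunk toward homogeneity. The reported conditional
average treatment effect (CATE) is `-tau(x)`: predicted HbA1c on SGLT2i
minus predicted HbA1c on GLP1-RA, in mmol/mol — negative favours SGLT2i.
Around the model sit:

* a synthetic-cohort generator with confounded assignment, a known
  treatment-effect surface (oracle `true_cate`) and the published baseline
  table's covariate marginals;
* study eligibility filters, outcome ascertainment (closest HbA1c to 12
  months within 3–15) and a stratified 60:40 development/validation split;
* a probit tree-ensemble propensity model with cross-validated
  discrimination;
* Dirichlet-sparsity variable selection from splitting probabilities,
  best-linear-projection importance, and clinical benefit subgroups
  (0–3, 3–5, > 5 mmol/mol toward either drug);
* the calibration validation framework: decile-of-predicted-CATE subgroup
  ATEs by spline-adjusted Bayesian regression, with propensity-matched
  sensitivity estimators and SMD balance tables;
* a pipeline (`run_pipeline()`) persisting every stage's artifacts, plus a
  thin CLI wrapper at `inst/scripts/bcfselect-pipeline.R`.

## Worked example

```r
library(bcfselect)

# a synthetic cohort with known ground truth, filtered to study eligibility
cohort <- generate_cohort(generator_config(n = 3400, seed = 21))
elig   <- apply_eligibility(cohort)
cc     <- complete_cases(elig$cohort,
                         union(mu_predictor_set(), full_predictor_set()))
cc     <- head(cc, 2000)

ps <- fit_propensity(cc, config = propensity_config(m = 100, n_iter = 600,
                                                    n_burn = 300, seed = 2))
ps
#> Probit tree-ensemble propensity fit
#>   n = 1863, trees = 100, retained draws = 300
#>   discrimination AUC = 0.624 (in-sample 0.746)
#>   pihat range: [0.043, 0.758]

# sparse selection fit, then the parsimonious final model
sel_fit <- fit_bcf(cc, pihat = ps$pihat,
                   config = bcf_config(m_mu = 50, m_tau = 20, n_iter = 3000,
                                       n_burn = 1500, sparsity = TRUE,
                                       seed = 3))
sel     <- select_variables(sel_fit)
mu_sel  <- union(setdiff(sel$variable[sel$forest == "prognostic" & sel$selected],
                         "pihat"), "outcome_month")
tau_sel <- sel$variable[sel$forest == "effect" & sel$selected]

fit <- fit_bcf(cc, mu_sel, tau_sel,
               config = bcf_config(m_mu = 50, m_tau = 20, n_iter = 5000,
                                   n_burn = 2500, n_thin = 5, n_chains = 2,
                                   include_pihat_in_mu = FALSE, seed = 4))
fit
#> Bayesian causal forest fit
#>   n = 1863 (GLP1-RA 486, SGLT2i 1377), retained draws = 1000
#>   forests: 50 prognostic + 20 treatment-effect trees
#>   posterior mean noise SD = 14.56 mmol/mol
#>   display CATE (SGLT2i - GLP1-RA): mean 0.41, SD 2.14 mmol/mol

cate <- predict_cate(fit)
cor(cate$cate_mean, cc$true_cate)   # oracle check, synthetic data only
#> [1] 0.631

table(assign_benefit_subgroups(cate))
#>  SGLT2i benefit >5 SGLT2i benefit 3-5 SGLT2i benefit 0-3
#>                  4                 65                847
#> GLP1-RA benefit 0-3 GLP1-RA benefit 3-5 GLP1-RA benefit >5
#>                 602                 345                  0
```

The cross-validated propensity AUC of 0.62 reflects the generator's
confounding by indication; the fitted noise SD recovers the generator's 15
mmol/mol; and the effect-forest selection retains sex and baseline HbA1c,
the generator's dominant modifiers, alongside some desk-scale noise. The
subgroup counts show how predictions convert into clinically thresholded
treatment-benefit groups; `autoplot(cate)` draws the CATE distribution. The
oracle correlation of 0.63 on this single cohort draw is typical of the
replicate spread at this sample size (see the methods vignette).

An end-to-end run with selection, final refit and held-out decile
calibration against covariate-adjusted subgroup ATEs:

```r
res <- recovery_run(seed = 1)
round(c(corr = res$corr, slope = res$slope, covered = res$covered), 4)
#>    corr   slope covered
#>  0.7782  0.9389  8.0000
```

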