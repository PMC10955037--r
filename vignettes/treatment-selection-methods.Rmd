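---
title: "Individualised treatment selection with Bayesian causal forests: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualised treatment selection with Bayesian causal forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Two glucose-lowering drug classes, SGLT2 inhibitors (SGLT2i) and GLP-1
receptor agonists (GLP1-RA), have similar average efficacy on 12-month
glycaemic control (HbA1c) but respond differently across patients. Given
routine clinical features measured at the time of prescribing, the package
estimates each individual's *conditional average treatment effect* (CATE):
the expected difference in achieved 12-month HbA1c between initiating one
class or the other. Throughout, the display convention is

> CATE = predicted HbA1c on SGLT2i − predicted HbA1c on GLP1-RA,

so negative values favour SGLT2i (lower achieved HbA1c there) and positive
values favour GLP1-RA.

Because treatment in observational data is assigned by indication (for
example, GLP1-RA users have markedly higher BMI), naive arm comparisons are
confounded; and because each patient receives only one drug, the individual
counterfactual is never observed, making validation of CATE predictions a
design problem of its own. The package implements the full workflow:
synthetic cohorts with known ground truth, eligibility filtering, propensity
estimation, the causal forest outcome model, variable selection and
importance, benefit subgrouping, and subgroup-level calibration validation.

# The outcome model

`fit_bcf()` fits a Bayesian causal forest: with $z_i = 1$ coding GLP1-RA,

$$ y_i = \mu(x^{\mu}_i) + \tau(x^{\tau}_i)\, z_i + \varepsilon_i, \qquad
   \varepsilon_i \sim \mathcal N(0, \sigma^2), $$

where $\mu$ (the prognostic surface) and $\tau$ (the treatment-effect
surface) are independent sums of regression trees. The displayed CATE is
$-\tau(x)$. The two ensembles are deliberately asymmetric:

* **Prognostic forest**: `m_mu = 200` trees (desk-scale analyses in this
  package use 50), depth prior $p(\text{split at depth } d) = \eta (1+d)^{-\beta}$
  with $\eta = 0.95$, $\beta = 2$, and the standard leaf prior
  $\mathcal N(0, (0.5/(k\sqrt{m_\mu}))^2)$ on the min–max-scaled outcome
  with $k = 2$.
* **Effect forest**: fewer (`m_tau = 50`, desk scale 20) and much shallower
  trees ($\eta = 0.25$, $\beta = 3$), so the effect surface is shrunk toward
  homogeneity and only splits with clear likelihood support survive. Its
  leaf scale is not fixed: it carries a half-normal hyperprior with scale
  $\mathrm{sd}(y_{\text{scaled}})/\sqrt{m_\tau}$, so that two prior standard
  deviations of the total effect surface span twice the marginal outcome SD.

The sampler is a backfitting MCMC written in C++: each tree receives a
grow/prune/change proposal (probabilities 0.4/0.4/0.2; cutpoints drawn
uniformly from the observed values of the proposed variable) evaluated on
its partial residual, accepted by Metropolis–Hastings with the conjugate
normal leaf prior integrated out; leaf values are then drawn from their
conjugate posteriors, and $\sigma^2$ from its scaled-inverse-$\chi^2$ full
conditional ($\nu = 3$, scale calibrated so the prior puts probability 0.9
below the marginal SD of the scaled outcome). The effect forest enters the
likelihood only through treated rows; its trees still predict for everyone.

Two sampler details matter in practice and are worth calling out:

* **Scale funnel.** The effect-forest leaf scale and its tree structure are
  mutually reinforcing: a small scale suppresses splits and a split-free
  forest keeps the scale small. Alongside the Gibbs-style update of the
  scale we therefore run a parameter-expansion move that proposes
  multiplying every effect leaf *and* the leaf scale by a common factor,
  accepted against the treated-row likelihood, the half-normal hyperprior
  and the log-scale Jacobian. This lets chains cross between the
  no-heterogeneity and heterogeneity modes.
* **Multiple chains.** `bcf_config(n_chains = )` pools retained draws of
  independent chains (seeded `seed`, `seed + 1`, ...). Posterior-mean CATE
  estimates at moderate sample sizes benefit noticeably from pooling.

With `include_pihat_in_mu = TRUE` (the default) the estimated propensity
score enters the prognostic predictor set, the standard guard against
regularisation-induced confounding in this model family. The outcome-month
covariate enters the prognostic surface only — follow-up timing modifies
achieved HbA1c, not the arm contrast — and is fixed at 12 months at
prediction time.

# Propensity model

`fit_propensity()` estimates $\hat\pi_i = P(z_i = 1 \mid x_i)$ with a probit
tree ensemble fitted by truncated-normal latent augmentation (fixed latent
variance 1, leaf prior SD $3/(k\sqrt m)$). The forest prior keeps fitted
probabilities away from 0 and 1 even under perfect separation. Because a
flexible in-sample fit is optimistic about discrimination, the reported AUC
is cross-validated (5 folds by default) from out-of-fold posterior-mean
probabilities; the in-sample AUC is reported alongside.

# Sparsity and variable selection

With `sparsity = TRUE`, each forest's split-variable distribution $s$ gets a
Dirichlet prior with total concentration 1 (an optional discrete-grid
hyperprior update of the concentration, with $a/(a+P) \sim$ Beta(0.5, 1), is
available via `conc_update`), updated conjugately each iteration from the
current split counts. `select_variables()` averages the retained
split-probability draws, aggregates the indicator columns of categorical
predictors back to their parent variable, and retains variables whose
posterior-mean splitting probability exceeds the uniform benchmark — for a
variable occupying $k$ of the $P$ encoded columns, $k/P$ (reducing to $1/p$
when every candidate is one column). The benchmark is per-variable because a
five-level categorical holds five columns' worth of prior splitting mass; a
single shared $1/p$ would systematically over-select multi-level factors.
The sparse total concentration matters at desk scale: the shallow effect
forest may carry only a handful of splits, and a flat per-column
concentration then leaves every variable's posterior mean hovering at the
benchmark, admitting noise variables.

Variable importance uses the best linear projection
(`best_linear_projection()`): least squares of the posterior-mean display
CATE on internally standardized covariates, with relative importance
$|\beta_j| / \sum_k |\beta_k| \times 100$. The percent scale is a
presentation choice (the literature reports percent importance without a
formula); coefficients are also reported in mmol/mol per SD.

# Validation framework

True CATEs are unobservable, so validation compares *subgroup-level*
quantities: individuals are binned by decile (or quintile, for small
cohorts) of predicted CATE, and within each bin the average treatment effect
is estimated by Bayesian linear regression of the outcome on the treatment
indicator plus the full covariate set, continuous covariates expanded to
3-knot restricted cubic splines (knots at the 10th/50th/90th percentiles —
standard practice where only "3 knots" is specified). The conjugate
normal–inverse-gamma prior is diffuse by default, so the posterior mean
coincides with least squares — which pins the estimator contract and lets
noise-free oracles be exact. Sensitivity estimators repeat the comparison
with greedy 1:1 propensity matching (caliper 0.2 SD of the logit propensity,
seed-fixed processing order; both stand-in defaults, documented rather than
asserted) with and without regression adjustment.

`calibration_summary()` then regresses the subgroup ATEs on the subgroup
mean predicted CATEs by inverse-variance-weighted least squares. A
well-calibrated model has slope 1 and intercept 0, and most subgroup
credible intervals cover the bin's mean prediction.

Two small-sample facts shape how calibration should be read, and they pull
in opposite directions. Binning a cohort by predictions fitted to *that same
cohort's outcomes* selects on noise correlated with the outcome, inflating
the apparent slope (in-sample optimism); binning an *independent* cohort by
noisy predictions attenuates the slope (errors-in-variables dilution).
Both effects vanish at registry scale but are material at a few thousand
patients. `recovery_run()` therefore evaluates calibration on an
independently generated probe cohort, uses pooled chains to cut prediction
noise, and — because posterior self-calibration is an *on-average* property
across cohort draws — the acceptance checks summarise replicate runs
(median slope, mean correlation) rather than a single draw.

# The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of a primary-care
cohort of people with type 2 diabetes initiating SGLT2i or GLP1-RA:

* **Covariates.** Continuous biomarkers come from a Gaussian copula with
  truncation to physiological ranges; marginal means and SDs are the
  published baseline table's arm-size-weighted mixtures (for example BMI
  34.6 kg/m², SD 7.15; baseline HbA1c 77.3 mmol/mol, SD 17). Binary,
  categorical and ordinal covariates (sex, ethnicity, smoking, deprivation,
  drug-count histories, comorbidity flags) are drawn independently with the
  table's mixture probabilities. Truncation shifts moments slightly, so
  fidelity checks compare against the truncated-normal moments the
  specification implies, not the nominal ones.
* **Assignment.** $z \sim \text{Bernoulli}(\text{expit}(\alpha + x^\top\gamma))$
  with coefficients calibrated once, at large n, so the default cohort
  reproduces the published arm-specific BMI means (37.3 GLP1-RA vs 33.7
  SGLT2i, the dominant channelling signal) and a GLP1-RA fraction near 0.25;
  prior drug counts, sex, eGFR, baseline HbA1c and age contribute smaller
  amounts. Setting `assignment_coefs` to an intercept only yields a
  randomised cohort.
* **Outcome.** $y = m(x) + t(x) z + \mathcal N(0, 15)$ in mmol/mol. The
  prognostic surface is anchored on baseline HbA1c (≈ 0.58 per mmol/mol)
  with smaller contributions from age, eGFR, therapy count, duration and a
  small linear drift in the outcome month (a stand-in, not an estimate:
  no timing effect is reported for these data; the drift exists so the
  outcome-month covariate is testably non-null). The effect surface
  $t(x)$ is the GLP1-RA effect; its sex coefficient (−4.4, i.e. a 4.4
  mmol/mol greater GLP1-RA response in women) matches the reported trial
  replication, while the baseline HbA1c, eGFR, therapy-count and BMI
  modifiers (all pushing toward SGLT2i when high) are free parameters set
  once to give a display-CATE SD near 3 mmol/mol — of the order implied by
  the reported benefit-subgroup proportions. The oracle columns `true_cate`
  ($-t(x)$) and `true_mu` ($m(x)$) exist only in synthetic data.
* **Secondary outcomes.** 12-month weight change defaults to −4 kg (SGLT2i)
  vs −2 kg (GLP1-RA) with 5 kg noise; 6-month discontinuation has a 15%
  base rate, decreasing in the predicted benefit of the received drug.
* **Timing and missingness.** Outcome month is uniform on [3, 15];
  missingness is MCAR with modest per-field rates (largest for the outcome
  HbA1c, mirroring routine-care follow-up testing).

What the generator does *not* emulate — informative missingness,
longitudinal prescription churn, measurement error in covariates,
drug-subtype heterogeneity, calendar trends — bounds what passing tests
show: they demonstrate that the machinery recovers known structure under
the stated assumptions, not that the model is correct for any real
registry.

# Eligibility and splitting rules

`apply_eligibility()` applies the study rules in a fixed order (same-day
multiple initiation, < 61 days since a prior therapy start, first-line use,
insulin co-treatment, end-stage renal disease, missing baseline HbA1c,
baseline HbA1c < 53 mmol/mol strict, missing outcome HbA1c), logging
per-rule exclusions; the order affects per-rule counts but not the total.
`ascertain_outcome()` takes the measurement closest to month 12 within
[3, 15] (bounds inclusive), equidistant ties resolving to the earlier
month — a deterministic choice where none is stated. `split_dev_val()`
splits 60:40 stratified by drug class with round-half-up per-stratum counts
and a mandatory seed. Analysis is complete-case (`complete_cases()`); the
sampler does not handle missing data.

# Numerical choices and degenerate inputs

* Outcomes are min–max scaled inside `fit_bcf()`; all leaf-scale defaults
  are on that scale and results are transformed back.
* Splits use `x <= cutpoint`; candidate cutpoints are the observed unique
  values (at most `max_cuts = 100` quantiles), excluding the maximum, and a
  proposal leaving a child with fewer than `min_leaf = 5` training rows is
  rejected.
* Benefit subgroups: the sign of the display CATE picks the favoured drug,
  with exactly zero assigned to the SGLT2i side (measure-zero, documented);
  absolute values are binned by the 3 and 5 mmol/mol thresholds, boundaries
  belonging to the lower bin. Decile bins break ties by stable input order.
* `update_split_probs()` with all-zero counts returns a symmetric Dirichlet
  draw; a degenerate all-equal selection input selects nothing and warns.
* Unit conversion uses NGSP% = 0.09148 × IFCC + 2.152.

# Desk-scale problem sizes

The shipped tests and the acceptance script run everything at desk scale,
chosen so the full suite completes in minutes on one CPU: development
cohorts of 2,000 complete cases (50 prognostic + 20 effect trees, 3,000 to
5,000 iterations, 2 pooled chains for final fits), probe cohorts of about
4,700 complete cases for calibration, 50 replicates of n = 500 for null
coverage, and 10 replicates of n = 1,000 for selection power. At these sizes
the per-cohort realized effect-modification signal varies substantially, so
replicate summaries are the meaningful outputs; single-cohort numbers should
be read with that variability in mind.

# Known limitations

* The effect forest learns from treated rows only (the $\tau z$
  parameterisation); very unbalanced arms weaken effect estimation.
* Multi-arm treatments, non-Gaussian outcomes and within-sampler missing
  data handling are out of scope.
* The Bayesian logistic model for discontinuation is a normal approximation
  at the maximum-likelihood fit; with separation or empty cells the
  affected contrasts are flagged not-estimable rather than regularised.
* Posterior-mean CATE estimates at a few thousand patients are strongly
  shrunken; their correlation with the truth is typically around 0.7 on the
  default generator, and honest out-of-sample calibration requires the
  replicate-level reading described above.
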