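---
title: "Small area estimation of district prevalence: models, design choices, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small area estimation of district prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

National household surveys are powered for national and regional estimates;
at the district level their samples (often well under a thousand
respondents, sometimes under fifty) are too small for design-based
estimation alone. `saeprev` implements the standard small-area-estimation
(SAE) toolkit for a binary outcome such as HIV status: design-weighted
direct estimation, an area-level (Fay-Herriot) linear mixed model on the
logit scale, and a unit-level random-intercept logistic model with
empirical best prediction, together with the diagnostics used to compare
them and a synthetic survey generator for evaluating the whole pipeline.

## The three estimators

**Direct (Hájek) estimator.** For district $i$ with sampled outcomes
$y_{ij}$ and design weights $w_{ij}$,
$$\hat p_i = \frac{\sum_j w_{ij} y_{ij}}{\sum_j w_{ij}}.$$
Its variance is estimated by Taylor linearization with the district as
stratum and the cluster (PSU) as resampling unit, under the
with-replacement approximation with an $n_{\mathrm{PSU}} /
(n_{\mathrm{PSU}}-1)$ correction. The `survey`-package conventions are
followed, but the estimator is implemented directly here and checked in the
test suite against a closed-form two-PSU case and a Monte-Carlo oracle.
Districts with a single sampled PSU get no variance (flagged, with a
warning); districts with $\hat p_i \in \{0, 1\}$ keep their direct estimate
but are excluded from the area-level model input, where the logit transform
is undefined. Normal-theory intervals $\hat p_i \pm 1.96\,\mathrm{se}$ are
truncated to $[0,1]$ — for very small districts this reproduces the
familiar degenerate $(0,1)$ interval rather than hiding it.

**Area-level model.** On the logit scale, with
$\hat\theta_i = \mathrm{logit}(\hat p_i)$ and delta-method sampling
variance $\psi_i = \mathrm{se}_i^2 / (\hat p_i(1-\hat p_i))^2$ treated as
known,
$$\hat\theta_i = \mathbf z_i'\boldsymbol\beta + v_i + e_i, \qquad
v_i \sim N(0, \sigma_v^2),\; e_i \sim N(0, \psi_i),$$
and the EBLUP is the convex combination
$\hat\theta_i^{FH} = \gamma_i \hat\theta_i + (1-\gamma_i)\mathbf
z_i'\hat{\boldsymbol\beta}$ with
$\gamma_i = \hat\sigma_v^2 / (\hat\sigma_v^2 + \psi_i)$. $\sigma_v^2$ is
estimated by bounded one-dimensional profile maximization of the REML
criterion by default (REML reduces the downward bias of the variance
component at moderate numbers of districts); ML is used whenever models
with different fixed effects are compared by AIC, counting the variance
component as one parameter. MSEs are the Prasad-Rao decomposition
$g_1 + g_2 + 2g_3$ ($g_1 = \gamma_i\psi_i$; $g_2$ the
coefficient-estimation term; $g_3$ the variance-estimation term using the
asymptotic variance $2/\sum_j (\hat\sigma_v^2+\psi_j)^{-2}$), with the
Datta-Lahiri bias-correction term added under ML. Prevalence-scale output
uses $p = \mathrm{expit}(\theta)$, the delta method
$\mathrm{mse}_p = \mathrm{mse}_\theta\,(p(1-p))^2$, and intervals formed on
the logit scale and back-transformed, so they always lie inside $(0,1)$.
Back-transformation choices are not dictated by the estimator itself; the
logit-symmetric interval was chosen because it respects the scale on which
the model is linear and normal.

**Unit-level model.** For individual $j$ in district $i$ with covariates
$\mathbf x_{ij}$,
$$\mathrm{logit}\,P(y_{ij}=1) = \mathbf x_{ij}'\boldsymbol\beta + v_i,
\qquad v_i \sim N(0, \sigma_v^2),$$
fitted by maximum likelihood with the random intercept integrated out by
adaptive Gauss-Hermite quadrature. A Bernoulli outcome has no separate
unit-level residual; all unit-level variation is the Bernoulli variation
itself. The district prevalence predictor is the empirical best predictor
over the finite population,
$$\hat p_i = \frac{1}{N_i}\Big(\sum_{j\in S} y_{ij} +
\sum_{j\in S'}\hat p_{ij}\Big),$$
where $S$ is the sampled set, $S'$ the non-sampled units of the district
frame, and $\hat p_{ij} = \mathrm{expit}(\mathbf
x_{ij}'\hat{\boldsymbol\beta} + \hat v_i)$ a plug-in prediction at the
empirical-Bayes mode $\hat v_i$ (districts absent from the fitting sample
use $\hat v_i = 0$). The plug-in form is used because it is the standard
printed form of the predictor; integrating over the conditional
distribution of $v_i$ changes third-decimal quantities at these problem
sizes.

Two deliberate modelling positions deserve emphasis. First, **survey
weights are not used in fitting the unit-level model**: it is an unweighted
superpopulation model, so under informative designs its estimates describe
the model, not the design — users combining it with heavily unequal
weights should be aware of this. Second, $\psi_i$ is treated as known in
the area-level model, as is conventional; no generalized variance function
smoothing is applied to the raw $\psi_i$ (a possible extension).

## Bootstrap MSE for the EBP

The EBP's MSE is estimated by a finite-population parametric bootstrap:
with the fitted $(\hat{\boldsymbol\beta}, \hat\sigma_v^2)$ held fixed, each
replicate draws fresh district effects $v_i^* \sim N(0,\hat\sigma_v^2)$ and
outcomes $y_{ij}^*$ for *every* unit of the frame, records the replicate's
finite-population truth $p_i^* = \bar y_i^*$, refits the model on the
original sampled positions (fixed design, random outcomes), recomputes the
EBP, and averages the squared deviations. Intervals are
$\hat p_i \pm 1.96\sqrt{\widehat{\mathrm{mse}}}$ truncated to $[0,1]$. The
default is $B = 200$ replicates; the whole procedure is reproducible from
one seed, and a run fails loudly if more than 20% of replicates cannot be
refitted.

Refitting a GLMM hundreds of times dominates the cost, so the package has
two interchangeable engines for the likelihood: `lme4::glmer` (the default
for user-facing fits) and an internal adaptive-quadrature ML fitter
(`engine = "agq"`) whose gradient is the posterior-expected score computed
with the same quadrature. Bootstrap refits always use the internal engine,
warm-started at the fitted parameters. The two engines agree to roughly
three decimals on fixed effects and variance components in the test suite,
and the quadrature itself is checked against 201-point brute-force
trapezoid integration of the per-district marginal likelihood (agreement to
1e-6). Mode-finding uses Newton steps with per-district step halving —
undamped Newton can cycle in the flat tails of the logistic likelihood, and
a single diverged mode poisons a bootstrap MSE.

## Comparison diagnostics

`compare_estimates()` aligns the three per-district series and computes the
conventional SAE evaluation battery: seven-number summaries (type-7
quantiles), coefficients of variation ($100\cdot\mathrm{se}/\hat p$, with
root-MSE standing in for the SE of model-based estimates), the fraction of
districts deemed reliable by the strict CV < 20% convention, OLS
regressions of each model-based series on the direct series (slope below 1
is the shrinkage signature; high $r^2$ indicates consistency), and percent
precision gains $100(1-\mathrm{mse}_{\mathrm{model}}/
\mathrm{var}_{\mathrm{direct}})$, taking the direct estimator's MSE to be
its variance (design unbiasedness). Districts missing a series are dropped
pairwise and counted.

## What the synthetic generator emulates — and what it does not

The generator builds finite populations of ~70 districts of 2,000-20,000
individuals partitioned into enumeration-area-like clusters (log-normal
sizes around $N_i/40$, so PPS sampling is non-trivial), draws five
categorical risk covariates (sex, age group, education, marital status,
partner count) from the marginal distributions observed in a national
population-based HIV survey — with a mild district-level composition tilt
(`composition_sd = 0.2`, a logistic-normal perturbation of the national
marginals per district) so districts differ in age, sex and education
structure the way urban and rural districts do — assigns district effects
on the logit scale ($\sigma_v = 0.5$ by default), and generates outcomes
from the unit-level model with a default coefficient vector chosen so that
national prevalence is about 6% and district prevalences span roughly
0.02-0.15 — the scale of the motivating application. Samples are drawn by systematic PPS of
clusters (with certainty handling) and simple random sampling of 25
individuals within clusters, giving exactly calibrated self-weighting
designs with district samples of roughly 50-500. The area-level covariate
is a biased, noisy logit-scale proxy of true prevalence
($z_i = \mathrm{logit}(p_i) + 0.3 + N(0, 1.0^2)$), emulating routine
antenatal-care surveillance: correlated with the truth but systematically
offset and weakly informative. The noise level was calibrated so that the
default configuration reproduces the diagnostic behaviour documented for
real ANC covariates — a strongly smoothed area-level series (bias-regression
slope well below the unit-level model's) whose dispersion falls below both
the unit-level and direct series. The unit-level auxiliary frame is a covariate-only
random subsample per district (475 units by default), emulating annual
community-survey rounds.

Deliberate simplifications, hence limits on what passing tests show about
real data: within a district, covariates are drawn independently of each
other (only marginals were available, so no covariate-covariate
correlation, e.g. between education and age); the ANC proxy is
generated at district level rather than through a pregnant-women
subpopulation; there is no non-response, no weight calibration or raking,
and no household structure; and district effects are spatially independent,
whereas real neighbouring districts are correlated. The generator is a
test bed for the estimators' statistical machinery, not a demographic
model of any country.

## Numerical choices

* FH profile maximization: `optimize()` on $[0, U]$ with $U$ grown
  adaptively, convergence tolerance 1e-10 on $\sigma_v^2$, and an explicit
  comparison against the boundary $\sigma_v^2 = 0$ (truncation, no ad-hoc
  floor). When some $\psi_i$ is numerically zero the search is kept away
  from the singular point by a 1e-6 lower bound, and linearization
  variances below 1e-14 are snapped to exact zeros.
* Quadrature: 15 adaptive Gauss-Hermite nodes for user-facing fits, 7 by
  default for bootstrap refits (5 in the heaviest calibration study) — the
  refit starts at the fitted optimum, where low-order quadrature is
  accurate.
* The internal engine maximizes the marginal likelihood with a
  gradient-based quasi-Newton method (PORT routines via `nlminb`, with a
  BFGS polish if it reports false convergence), using the
  posterior-expected score as the analytic gradient; repeated fits in
  simulation studies can warm-start from a previous optimum (`start`).
* Ties in AIC selection are broken toward fewer parameters.
* Stage seeds are derived from one master seed by stable string hashing of
  stage names, so adding a stage never perturbs earlier stages' streams.

## Evaluation scales

The test suite's simulation studies use these problem sizes, chosen to
make overnight-scale Monte-Carlo answerable in minutes while keeping each
study at the structure it evaluates: area-model parameter recovery and
EBLUP dominance at 70 districts x 200 replicates; unit-model parameter
recovery at 70 districts x 200 units x 100 replicates; bootstrap
calibration as a nested study (100 outer replicates x B = 100) at 20
districts of 100 units with half sampled; and the three-estimator
comparison with a 100-replicate dispersion-ordering check at 70 districts
with populations of 1,000-5,000 and district samples of 50-250, plus one
full default-scale pipeline run (B = 40) for the CV and precision-gain
pattern. The reproduction script runs the full default-scale pipeline (70
districts, populations 2,000-20,000, B = 100).

## Known limitations

Raw $\psi_i$ enter the FH model unsmoothed; the unit-level model ignores
design weights; no spatial or multivariate extensions; MSEs of area-level
estimates for districts excluded from fitting are synthetic-prediction
variances that ignore covariate-model misspecification; and the bootstrap
MSE conditions on $(\hat{\boldsymbol\beta},\hat\sigma_v^2)$, so it
understates uncertainty from estimating those parameters (the calibration
study bounds this within a factor of two at the evaluated scales).
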