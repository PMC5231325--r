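---
title: "Selecting the number of latent classes with overfitted mixtures"
author: "overmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the number of latent classes with overfitted mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(overmix)
```

## The model and the selection problem

A finite mixture writes the density of an observation as
$f(y) = \sum_{j=1}^{K} \lambda_j f_j(y \mid \theta_j, \gamma)$, with
nonnegative proportions $\lambda_j$ summing to one, class-specific
parameters $\theta_j$ and (optionally) parameters $\gamma$ shared by all
classes. Two concrete families are implemented:

* a **univariate location–scale Gaussian mixture**,
  $f_j = N(\mu_j, \sigma_j^2)$, and
* a **growth mixture model** (latent-class linear mixed-effects model)
  for longitudinal data,
  $y_{it\mid j} = \theta_{j0} + b_{i0} + (\theta_{j1} + b_{i1})\,
  t_{it} + \epsilon_{it}$, where the subject random effects
  $(b_{i0}, b_{i1})$ are Gaussian and $\epsilon_{it} \sim
  N(0, \sigma^2)$. Common covariate effects (e.g. age or season in the
  blood-donor application this model family comes from) enter as
  additional fixed-effect columns shared by all classes.

The practical question is $K$: how many latent classes do the data
support? The package's core answer is the *overfitted-mixture
criterion*: fit one model with deliberately many components
($K_{\max} = 10$ by default) under a *sparse* symmetric
Dirichlet($\alpha$) prior on the proportions. Asymptotic theory for
overfitted mixtures says that when $\alpha < d/2$, with $d$ the number
of class-specific parameters, the proportions of the superfluous
components concentrate at zero. At each MCMC iteration $m$ the number of
"non-empty" components is counted as
$$K^{(m)} = K_{\max} - \sum_{j=1}^{K_{\max}}
  I\{N_j^{(m)}/N \le \psi\},$$
where $N_j^{(m)}$ is the number of units allocated to component $j$, $N$
the number of units, and $\psi \in \{0, 0.01, 0.02, 0.05\}$ a small
cut-off fraction (the inequality is non-strict, so a class holding
exactly $\psi N$ units counts as empty). The estimate of $K$ is the
posterior mode of $K^{(m)}$; ties are broken toward the smaller $K$. For
longitudinal models the exchangeable unit is the *subject*, so $N_j$ and
$N$ count subjects.

Competing criteria are provided for comparison: the mixture-adapted
deviance information criteria
$\mathrm{DIC}_3 = -4\,E[\log f(y\mid\theta)\mid y] + 2\log \hat f(y)$
(with $\hat f(y_i)$ the posterior-mean mixture density of observation
$i$) and
$\mathrm{DIC}_4 = -4\,E[\log f(y, Z\mid\theta)\mid y] +
2\,E_Z[\log f(y, Z \mid E[\theta \mid y, Z])\mid y]$ computed from the
same Gibbs output, and $\mathrm{BIC} = -2\log f(y\mid\hat\theta) +
g\log n$ computed from maximum-likelihood fits obtained by EM at each
candidate $K$.

## Priors and their hyperparameters

For the univariate mixture two prior families are available for
$(\mu_j, \sigma_j^2)$:

* **vague** (the recommended default): $\mu_j \sim N(0, 1000)$ and
  $\sigma_j^2 \sim U(0, 10)$;
* **hierarchical normal–gamma**: $\mu_k \mid b_0, \eta \sim
  N(b_0, \eta R^2)$ with $b_0 \sim N(m_0, 10^7)$ and
  $\eta \sim \Gamma(0.5, 0.5)$, where $m_0$ and $R$ are the median and
  range of the data; and $1/\sigma_k^2 \sim \Gamma(1.25, C_0)$ with
  $C_0 \sim \Gamma(0.25, 20/R^2)$. All gammas are shape–rate. Note the
  placement of $C_0$: it is the *rate* of the gamma prior on the
  precisions, which is what makes $C_0$ conditionally conjugate
  ($C_0 \mid \text{precisions} \sim \Gamma(0.25 + 1.25 K_{\max},
  20/R^2 + \sum_k \sigma_k^{-2})$). Writing the rate as a function such
  as $1/(2C_0)$ instead would make the $C_0$ update a
  generalized-inverse-Gaussian draw; we use the conjugate form of the
  originating shrinkage-prior construction.

For the growth model: fixed effects $\sim N(0, 10^3)$; residual
precision $\sim \Gamma(10^{-3}, 10^{-3})$ (an inverse-gamma on the
variance); the random-effect covariance $\Sigma$ has an inverse-Wishart
prior with scale $\mathrm{diag}(10^{-3})$ and 3 degrees of freedom in
the convention with density $\propto
|\Sigma|^{-(df+p+1)/2}\exp(-\mathrm{tr}(S\Sigma^{-1})/2)$; a single
random intercept instead gets a $\Gamma(10^{-3}, 10^{-3})$ prior on its
precision.

The Dirichlet hyperparameter $\alpha$ is the tuning knob that matters.
$d = 2$ for the univariate mixture (mean and variance), $d = 2$ for a
random-intercept growth model with common slope (intercept and
random-intercept variance) and $d = 5$ for a random-intercept-and-slope
model (two fixed effects plus three covariance entries). Values of
$\alpha$ slightly below the $d/2$ threshold select best in the
simulations; `recommended_alpha(d)` returns $0.85\,d/2$. For the
cut-off, $\psi$ between 0.02 and 0.05 is a good default; use smaller
$\psi$ when classes holding only a few percent of the population are of
substantive interest (a class whose true share equals $\psi$ sits
exactly on the boundary and is found only about half the time).

## Samplers

`run_gibbs_univariate()` is a systematic-scan Gibbs sampler with data
augmentation: allocations (log-space, max-subtracted), Dirichlet
proportions (small shapes drawn through the
$\Gamma(\alpha+1)\,U^{1/\alpha}$ representation in log space, stable
down to $\alpha = 10^{-5}$), conjugate normal means, and variances. The
variance conditional under the $U(0, 10)$ prior is an inverse-gamma
kernel truncated to the support; it is drawn by rejection from the
untruncated inverse-gamma when that is proper ($N_j \ge 3$) and by
inverse-CDF on a 512-point grid otherwise. Components with no allocated
observations draw from the prior, keeping the chain on the full
$K_{\max}$-dimensional space. No relabelling is done: the empty-class
count and the deviance criteria are label-permutation invariant.

`run_gibbs_growth()` is a blocked sampler: subject allocation from the
marginal likelihood with the random effects integrated out analytically
(Woodbury identities on the small $r \times r$ blocks, so the per-sweep
cost is linear in subjects and classes), then conjugate draws of random
effects, class fixed effects, common fixed effects, random-effect
covariances and the residual precision. A conditional-on-$b$ allocation
variant (`marginal_alloc = FALSE`) targets the same posterior and is
kept as a cross-check of the marginalization algebra.

Numerical/design choices, made once and kept:

* **Initialization.** Class means/intercepts start at data quantiles
  ("spread"), variances at the sample variance, hyperparameters at
  prior means; the first allocation sweep then distributes units over
  all components. An alternative "common" start (all classes at the
  pooled estimate) is available; selections on the benchmark scenarios
  are insensitive to this choice except where noted below.
* **Random-effect covariance structure.** With two or more random terms
  the covariance update is pooled across classes by default. An
  unstructured covariance updated per class lets a component shrink its
  covariance onto one or two subjects; such overfitted singleton
  components are sticky under Gibbs moves and inflate the non-empty
  count at $\psi = 0$. With the pooled update the count concentrates on
  the true number of classes across the whole $\alpha$ grid, matching
  the behaviour of the standard latent-class software this model family
  is usually fitted with. The single-random-intercept model keeps a
  class-specific variance (it is one of the $d = 2$ class-specific
  parameters and is not prone to the singleton pathology). The $d$ used
  for the $\alpha < d/2$ rule always counts the generating model's
  class-specific parameters.
* **Empty classes** always redraw from the prior; under the vague
  priors this means superfluous components are reborn only when a prior
  draw lands near the data, which is rare — exactly the mechanism the
  sparse-Dirichlet asymptotics rely on.
* **DIC4 plug-in.** $E[\theta \mid y, Z]$ is computed from conjugate
  closed forms given the allocation: Dirichlet mean for $\lambda$,
  conjugate normal mean for each $\mu_j$, and the conditional posterior
  mean of each $\sigma_j^2$ (grid integration on the truncated support
  under the uniform prior; inverse-gamma mean under the hierarchical
  prior). Components empty under $z^{(m)}$ use prior means.
* **EM.** `em_univariate()` uses 10 random starts (quantile start
  first), log-space responsibilities and a variance floor of
  $10^{-6}\,\mathrm{var}(y)$ against the unbounded-likelihood spike.
  `em_growth()` is an ECM with the random effects as missing data;
  every conditional M-step has a closed form, so the observed
  log likelihood is non-decreasing. Subjects sharing a design block are
  processed as one matrix group, so balanced panels fit in well under a
  second. Its covariance is shared across classes by default (the
  standard convention; `share_re_cov = FALSE` gives per-class
  covariances and adjusts the BIC parameter count).
* **BIC's $n$ for growth models** counts *subjects*, the exchangeable
  units, matching the convention of standard latent-class trajectory
  software; total rows are available via `bic_n = "rows"`. The choice
  is material: on the three-class random-slope benchmark the $K=3$
  versus $K=1$ deviance gain is ~65 while the penalty difference is
  $12\log(1200) \approx 85$ against $12\log(200) \approx 64$, so the
  rows convention would never select three classes.

## What the synthetic-data generators emulate

`mixture_scenario()` reproduces the benchmark designs exactly:
univariate scenarios with $n = 500$ and $K = 3$ means $(1, 2, 3)$ at
high/moderate/low separation ($\sigma$ = 0.25, 0.4, 0.7), a homogeneous
scenario, an unequal-proportion variant $(0.475, 0.475, 0.05)$, and
growth scenarios with 200 subjects $\times$ 6 occasions, intercepts
$(1, 2, 3)$, slopes $(-0.1, -0.2, -0.3)$ or a common $-0.2$, random
intercept SD 0.25, random slope SD 0.025 and residual SD 0.25. Where
the benchmark design leaves details unstated we fixed them once: the
time grid is $0, 1, \dots, 5$ (the simplest grid consistent with six
occasions per subject); tail outliers are placed 5 sample SDs beyond
the observed range (unambiguously outlying, configurable). Generating
labels are stored in a separate truth container and never reach any
fitting code.

The generators draw i.i.d. Gaussian classes with exactly the stated
parameters; they do not emulate skewness, heavy tails,
missing-at-random visits, irregular observation times or
covariate-dependent class membership. Passing benchmarks here therefore
says nothing about robustness to those features of real data — the
outlier variant (`add_tail_outliers()`) is the only departure from the
clean model that is exercised.

## Problem sizes used by the tests and the acceptance script

Success-rate cells are binomial proportions, so desk-scale replicates
bound the Monte-Carlo error: with 20 datasets one standard error is at
most 11.2 percentage points. The acceptance script uses 20 datasets per
univariate arm with 10,000 retained sweeps after 2,000 burn-in, and
10–20 datasets per growth arm with 5,000 retained sweeps after 1,000
burn-in. The test suite uses the same designs at 2,500 retained sweeps
(the selected mode is stable well before that) so the whole suite runs
in minutes. Full-size runs (50 datasets, 50,000 sweeps after 5,000
burn-in) are a flag away via `experiment_config()`.

## Known limitations

* The criterion inherits the knife-edge behaviour at $\psi$ equal to a
  true class share. On the unequal-proportion benchmark the chain often
  keeps a component covering the smallest class *plus* the adjacent
  tail, so the occupancy of the third component sits above the cut-off
  more often than the realized class size alone would suggest; we
  verified with an independent sampler (rjags, identical model) that
  this is a property of the stated model's posterior, not of this
  implementation.
* Only Gaussian components; no missing data; no class-predictive
  covariates in the membership model; no reversible-jump moves or
  marginal-likelihood estimation — $K_{\max}$ must be chosen large
  enough up front.
* With hierarchical (normal–gamma) priors the selection is markedly
  more sensitive to $\alpha$ than with vague priors; the vague family
  is the recommended default.
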