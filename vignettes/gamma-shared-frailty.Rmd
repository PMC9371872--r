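---
title: "Parametric gamma shared frailty models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric gamma shared frailty models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`gsfrailty` analyses clustered right-censored time-to-event data — the
motivating application is time to first birth of married women, clustered by
region of residence.  Subject $k$ in cluster $i$ has conditional hazard

$$h_{ik}(t \mid z_i) = z_i\, h_0(t)\, e^{x_{ik}'\beta},$$

a proportional-hazards model in which the cluster-level frailty $z_i$ acts
multiplicatively on the hazard.  Frailties are independent
$\mathrm{Gamma}(1/\theta,\ \mathrm{rate}\ 1/\theta)$ draws — mean 1,
variance $\theta$ — so $\theta = 0$ recovers independence and larger
$\theta$ means stronger unobserved regional heterogeneity.  The within-
cluster dependence this induces has the closed Kendall's-tau form
$\tau = \theta/(\theta+2)$ (`kendalls_tau()`).

Some formulations place the random effect additively on the log hazard,
$\exp(x'\beta + Z_i)$, while simultaneously putting a mean-one gamma law on
$Z_i$ itself; those two readings are incompatible.  We use the standard
multiplicative convention above, which is the one consistent with a mean-one
gamma frailty and with the frailty literature.

Censoring is assumed right, independent and noninformative.  Times are
positive reals in years; the package stores a single time column and leaves
the time origin (birth or marriage) to the analyst.

## Baseline families

Five baseline hazards are supported, all parameterized on the hazard scale:

| family | hazard $h_0(t)$ | survivor $S_0(t)$ |
|---|---|---|
| exponential | $\lambda$ | $e^{-\lambda t}$ |
| Weibull | $\lambda\gamma t^{\gamma-1}$ | $e^{-\lambda t^\gamma}$ |
| Gompertz | $\lambda e^{\theta t}$ | $\exp[(\lambda/\theta)(1-e^{\theta t})]$ |
| log-normal | $f/S$ | $1-\Phi((\log t-\mu)/\delta)$ |
| log-logistic | $e^\theta k t^{k-1}/(1+e^\theta t^k)$ | $1/(1+e^\theta t^k)$ |

Note the Weibull convention: $\lambda$ multiplies the cumulative hazard
($S = e^{-\lambda t^\gamma}$), *not* the $\,(t/\lambda)$ scale convention
used by `stats::dweibull`.  A hazard written as
$e^\theta k t^{k-1}/(1+e^\theta t^k)^2$ for the log-logistic family is a
density, not a hazard, given that survivor function; we implement the
standard $h = f/S$ form.  All likelihood work is done in log space, and the
Gompertz family takes its exponential limit analytically when
$|\theta| < 10^{-12}$ to avoid $0/0$.

## Marginal likelihood and maximum likelihood

For gamma frailty the cluster-level integral is closed form.  With $d_i$
events and $A_i = \sum_j H_0(t_{ij}) e^{x_{ij}'\beta}$ in cluster $i$,

$$L_i = \Big[\prod_{j:\delta_{ij}=1} h_0(t_{ij})e^{x_{ij}'\beta}\Big]
\frac{(1/\theta)^{1/\theta}\,\Gamma(1/\theta+d_i)}
     {\Gamma(1/\theta)\,(A_i+1/\theta)^{1/\theta+d_i}}.$$

Numerically, three regimes are used: the exact independence limit for
$\theta < 10^{-12}$; an expansion of the $\log\Gamma$ difference as
$\sum_{k=0}^{d_i-1}\log\frac{1+k\theta}{1+\theta A_i}$ for
$\theta < 10^{-4}$ (the naive $\log\Gamma(1/\theta+d)-\log\Gamma(1/\theta)$
difference loses all precision when $1/\theta \sim 10^{10}$); and the
direct $\log\Gamma$ form otherwise.  Continuity across the branch points is
property-tested, and the whole expression is tested against adaptive
quadrature of the frailty integral on random small datasets.

`fit_ml()` maximizes this marginal log-likelihood by multi-start BFGS on
unconstrained transforms (log for positive parameters, identity for real
ones; $\theta \ge 0$ via $\log\theta$).  Starts are (i) a data-driven start
(a least-squares probe of the Kaplan-Meier log cumulative hazard for the
shape, crude moments otherwise), (ii) a null/exponential-equivalent start,
and (iii) Gaussian perturbations of the first.  Standard errors come from
the numerically differentiated observed information at the optimum, mapped
to the natural scale by the delta method.  A fitted $\hat\theta < 10^{-4}$
is reported with a boundary flag instead of a standard error.  The optimizer
runs at relative tolerance $10^{-12}$; we rely on its convergence code
rather than a raw gradient-norm threshold, which is below finite-difference
noise at log-likelihood magnitudes of $10^4$.

`compare_ml()` ranks fits by $\mathrm{AIC} = -2\ell + 2P$ and also reports
$\mathrm{BIC} = -2\ell + P\log n$; both identities are asserted on every
fit.  The Weibull PH coefficients convert to the AFT scale as
$\beta_{\mathrm{AFT}} = -\beta_{\mathrm{PH}}/\gamma$
(`weibull_ph_to_aft()`), for comparison with AFT-reported software.

## Priors and the posterior

The default priors (`prior_spec()`) are vague and proper:

* coefficients and real-valued baseline parameters:
  $\mathrm{N}(0,\ 10^5)$;
* strictly positive baseline parameters: $\mathrm{Gamma}(1,\ \mathrm{rate}\
  0.001)$, i.e. mean 1000, variance $10^6$ — a "shape 1, scale 0.001, mean
  1000" description is only coherent if 0.001 is a *rate*, so shape/rate is
  used throughout;
* frailty precision $1/\theta$: $\mathrm{Gamma}(0.001,\ \mathrm{rate}\
  0.001)$, equivalently an inverse-gamma prior on $\theta$.

`log_posterior()` exposes the augmented-data target (complete-data
likelihood plus frailty densities plus priors); invalid states return
$-\infty$ rather than raising.

## Sampler architecture

`run_mcmc()` is a Metropolis-within-Gibbs sampler:

* **Frailties**: exact conjugate Gibbs draws,
  $z_i \mid \cdot \sim \mathrm{Gamma}(1/\theta + d_i,\ 1/\theta + A_i)$.
* **Coefficients, baseline parameters, $\log\theta$**: three random-walk
  Metropolis blocks on unconstrained scales.  Proposals are shaped by the
  Cholesky factor of the corresponding block of the ML covariance and
  scaled by a single per-block multiplier.

The Metropolis blocks target the *marginal* (frailty-integrated) posterior
rather than the augmented one.  The augmented target leaves an almost
unidentified direction — the overall frailty level against the baseline
scale $\lambda$ — along which a conditional random walk mixes very poorly
(we measured an effective sample size near 13 out of 4000 for the mean log
frailty).  Collapsing the frailties out of the acceptance ratio removes
that direction entirely while leaving the stationary distribution of
$(\beta, \Lambda_0, \theta)$ unchanged, and the per-iteration conditional
frailty draw still yields exact posterior samples of $z$.  In our fixtures
this raised effective sample sizes about five-fold at identical cost.

Proposal multipliers adapt only during burn-in (Robbins-Monro on the
acceptance rate, target 0.30, within the 0.25–0.40 band), so the
post-burn-in kernel is fixed and valid.  Chain 1 starts at the ML estimate;
later chains at overdispersed Gaussian perturbations of it.  Runs are
bitwise reproducible given the seed, with chain $c$ seeded as
`seed + 7919 (c-1)`.

Defaults mirror the emulated study's run design: 2 chains, 20,000 kept
iterations each after 1,000 burn-in, thinning 1.  (That study reports
42,000 stored samples, which corresponds to keeping the burn-in in the
count; we store the post-burn-in 2 × 20,000 and note the discrepancy.)

## Posterior summaries, MC error, DIC

`summarize_posterior()` reports pooled means, SDs, medians and equal-tailed
95% intervals.  The Monte Carlo error uses batch means — 50 batches per
chain, combined across chains — a reproducible estimator in the spirit of
the classic BUGS column, and each parameter is checked against the stopping
rule *MC error < 5% of the posterior SD*.  A parameter whose interval
excludes 0 is flagged, the usual significance convention for coefficient
tables.

`compute_dic()` reports $\bar D$ (posterior mean deviance), $\hat D$
(deviance at posterior means), $p_D = \bar D - \hat D$ and
$\mathrm{DIC} = \bar D + p_D$.  The deviance uses the marginal likelihood by
default so frailty and no-frailty models are comparable on one scale; a
conditional (plug-in frailty) focus is available as an option.  $\bar D$
caps the number of evaluated draws at 1000 (evenly thinned) for speed; the
cap is an explicit argument.

## Convergence diagnostics

`bgr_diagnostic()` implements the interval-based Brooks–Gelman ratio: the
width of the pooled central 80% interval divided by the mean within-chain
width, over expanding iteration windows (second half of each window).  This
is the variant WinBUGS plots, and it has the clean contracts the tests
assert: duplicated chains give exactly 1.0 (type-1 quantiles make the
pooled and within-chain intervals literally identical), iid chains fall
below 1.05, and separated chains blow past 1.5.  `convergence_plots()`
writes per-parameter history, density and BGR PNGs with deterministic
filenames.

## The synthetic-data generator

`scenario_spec()` + `generate_dataset()` emulate the cross-sectional
structure the analysis assumes: 11 regional clusters in the published
relative sizes (n = 8810 at the survey's own size), covariate categories at
the published marginal frequencies, gamma frailties with mean 1 and
variance $\theta$, event times drawn by inverting
$S(t\mid z, x) = \exp(-z H_0(t) e^{x'\beta})$, and independent uniform
administrative censoring whose window is calibrated by Monte-Carlo root
finding (common random numbers, fixed inner seed) to a 24.5% censored
fraction.  The calibration integrates over the frailty law by drawing a
frailty per subject, so it targets the *expected* censored fraction; any
single generated dataset still inherits the variability of its 11 realized
cluster frailties, about ±2 percentage points of censored fraction at the
default truth.  The default truth is the fitted regime of the emulated study:
Weibull shape 6.1, $\log\lambda = -17.75$, coefficients at the published
posterior means, $\theta = 0.95$.

What the generator does *not* emulate, deliberately: covariates are drawn
independently across variables (only marginals are published, not a joint
law); there are no survey weights or two-stage sampling effects; and the
censoring mechanism is an assumption (the emulated survey never states
one), recorded as such in the generation report.  Tests passing on these
fixtures therefore validate the estimators under the stated model, not the
full complexity of real survey data.

## Nonparametric components

Kaplan-Meier estimation (with Greenwood variance and simultaneous decrement
at ties), the log(-log)-inverted median confidence interval and the
unweighted K-sample log-rank test are delegated to the `survival` package
behind the package's own interfaces (`kaplan_meier()`, `median_survival()`,
`log_rank()`); the tests check them against hand-computed product-limit
values and an independently coded observed-minus-expected tabulation.  The
median CI method is a package choice — the emulated study does not state
one.  The median is defined as the smallest observed time with
$\hat S(t) \le 0.5$; when the curve never reaches 0.5 the median is
returned as `NA`, not an error.

## Problem sizes used by the tests

The shipped test-suite and acceptance-script runs use deliberately scaled
simulation sizes chosen to keep the whole suite quick while leaving all
checks well-powered: parameter recovery at $n = 3000$ with 2 × 4,000 kept
MCMC iterations; DIC model selection over 50 replicates at $n = 660$ with
single short chains; the MC-error rule on an $n = 800$ fixture at 2 ×
4,000; 1,000 null replicates for the log-rank type-I error.  These sizes
are the package's own fixture choices and are easy to scale up through the
same interfaces.

## Known limitations

* Only gamma frailty; no inverse-Gaussian, log-normal or positive-stable
  alternatives, no time-varying covariates, no left truncation or interval
  censoring.
* Complete-case only: rows with missing covariates are rejected with a
  row-indexed error.
* Random-walk Metropolis is adequate for the modest parameter counts here
  but would benefit from gradient-based samplers in much larger designs.
* The DIC of mixed-focus comparisons is only meaningful when every model in
  the comparison uses the same (marginal) deviance focus, which is the
  default.
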