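# gsfrailty

Parametric **g**amma **s**hared-**frailty** proportional-hazards models for
clustered right-censored time-to-event data, fitted by marginal maximum
likelihood and by Metropolis-within-Gibbs MCMC.

## The problem

In many demographic and epidemiological studies the subjects are grouped —
for example, married women grouped by region in a national survey, with the
outcome being the time to their first birth and roughly a quarter of the
observations right-censored at interview.  Subjects in the same group share
unmeasured conditions, so their event times are dependent; ignoring that
dependence biases hazard ratios and understates uncertainty.  The shared
frailty model makes the dependence explicit: subject $k$ of cluster $i$ has
hazard

$$h_{ik}(t \mid z_i) = z_i \, h_0(t)\, e^{x_{ik}'\beta},$$

where $h_0$ is a parametric baseline hazard (exponential, Weibull,
Gompertz, log-normal or log-logistic), $\beta$ are covariate effects, and
the cluster frailty $z_i \sim \mathrm{Gamma}(1/\theta, 1/\theta)$ has mean
1 and variance $\theta$.  $\theta$ measures unobserved heterogeneity
between clusters; the within-cluster Kendall's tau is $\theta/(\theta+2)$.

For gamma frailty the cluster integral is closed form, so the package fits
the model two ways on the same marginal likelihood:

* **Maximum likelihood** (`fit_ml`), with observed-information standard
  errors and AIC/BIC model comparison across baseline families
  (`compare_ml`);
* **Bayesian MCMC** (`run_mcmc`), with vague priors, exact conjugate Gibbs
  draws for the frailties, adaptive random-walk Metropolis blocks for the
  remaining parameters, posterior summaries with batch-means Monte Carlo
  errors (`summarize_posterior`), DIC comparison (`compute_dic`),
  Brooks-Gelman-Rubin diagnostics (`bgr_diagnostic`) and trace/density/BGR
  plots (`convergence_plots`).

Around the core model the package provides Kaplan-Meier estimation with
median survival intervals, the K-sample log-rank test, a validating
CSV/codebook data layer, a synthetic-data generator that emulates the
clustered survey structure (11 regions, published covariate marginals,
~24.5% censoring), and a pipeline driver (`run_pipeline`) that renders the
full table set of a typical analysis.

## Worked example

```r
library(gsfrailty)

# a synthetic survey-structured dataset: 11 regional clusters,
# Weibull baseline (shape 6.1), frailty variance 0.95, ~24.5% censoring
sc <- scenario_spec(n = 3000,
  marginals = list(residence = c(urban = 2077, rural = 6733),
                   media = c(no = 6280, yes = 2530),
                   contraceptive = c(yes = 4459, no = 4351)),
  beta = c("residence.rural" = 0.2112, "media.yes" = -0.1168,
           "contraceptive.no" = 0.1134),
  theta = 0.95, seed = 424)
g <- generate_dataset(sc)

fit <- fit_ml(g$dataset, "weibull", frailty = TRUE)
print(fit)
#> ML fit: weibull baseline, gamma shared frailty
#>                  estimate      se
#> lambda            0.00000 0.00000
#> gamma             6.01506 0.09782
#> residence.rural   0.18763 0.05028
#> media.yes        -0.06621 0.04688
#> contraceptive.no  0.11310 0.04271
#> theta             1.07816 0.40440
#> logLik -6120.760  AIC 12253.520  BIC 12289.558  (P = 6, n = 3000)

kendalls_tau(fit$estimates["theta"])   # within-cluster dependence
#>     theta
#> 0.3502617

ch <- run_mcmc(g$dataset, "weibull", iters = 4000, burnin = 1000,
               chains = 2, seed = 424, init = fit)
print(summarize_posterior(ch)[, c("parameter", "mean", "sd", "mc_error",
                                  "lower", "upper")], digits = 3)
#>          parameter      mean       sd mc_error     lower    upper
#> 1           lambda  3.41e-08 2.14e-08 8.06e-10  1.22e-08 8.75e-08
#> 2            gamma  6.00e+00 9.63e-02 2.94e-03  5.80e+00 6.18e+00
#> 3  residence.rural  1.87e-01 5.02e-02 1.85e-03  8.73e-02 2.89e-01
#> 4        media.yes -6.56e-02 4.57e-02 1.71e-03 -1.56e-01 2.58e-02
#> 5 contraceptive.no  1.14e-01 4.16e-02 1.54e-03  3.06e-02 1.97e-01
#> 6            theta  1.38e+00 6.39e-01 1.99e-02  6.11e-01 3.02e+00
```

The Weibull shape (`gamma`) is recovered within one standard error of the
generating 6.1 by both routes, every coefficient's 95% interval covers its
generating value, and the frailty-variance (`theta`) interval covers the
generating 0.95 — its point estimates run high here because, with only 11
clusters, the realized between-cluster variance of one dataset is itself
noisy.  Exponentiating a coefficient gives a hazard ratio:
`exp(0.1134) = 1.12` means never-users of contraception have a 12% higher
hazard of first birth than ever-users at the same covariates and frailty.
The small `mc_error` column (under 5% of each posterior SD) is the run-
length rule the sampler is tuned to meet.

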