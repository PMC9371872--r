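#' Gamma shared-frailty proportional-hazards model specification
#'
#' The conditional hazard of subject `k` in cluster `i` is
#' \deqn{h_{ik}(t \mid z_i) = z_i \, h_0(t) \, e^{x_{ik}'\beta},}
#' with cluster frailties \eqn{z_i \sim \mathrm{Gamma}(1/\theta,
#' \mathrm{rate}\, 1/\theta)} (mean 1, variance \eqn{\theta}).  \eqn{\theta =
#' 0} recovers the independent proportional-hazards model.
#'
#' @param baseline A [baseline_spec()].
#' @param beta Named numeric vector of regression coefficients (one per
#'   design column; may be length 0).
#' @param theta Frailty variance, `>= 0`.
#' @return An object of class `frailty_spec`.
#' @export
frailty_spec <- function(baseline, beta = numeric(0), theta = 0) {
  stopifnot(inherits(baseline, "baseline_spec"))
  b <- as.numeric(beta)
  names(b) <- names(beta)
  if (any(!is.finite(b))) stop("beta must be finite", call. = FALSE)
  if (!is.finite(theta) || theta < 0)
    stop("frailty variance theta must be >= 0", call. = FALSE)
  structure(list(baseline = baseline, beta = b, theta = as.numeric(theta)),
            class = "frailty_spec")
}

#' @export
print.frailty_spec <- function(x, ...) {
  cat("Gamma shared-frailty PH model\n")
  print(x$baseline)
  if (length(x$beta))
    cat("  beta:", paste(sprintf("%s=%.4g", names(x$beta), x$beta),
                         collapse = ", "), "\n")
  cat(sprintf("  frailty variance theta = %g (Kendall's tau = %.4g)\n",
              x$theta, kendalls_tau(x$theta)))
  invisible(x)
}

#' Conditional hazard given the cluster frailty
#'
#' `z * h0(t) * exp(x'beta)` — frailty acts multiplicatively on the hazard.
#'
#' @param spec A [frailty_spec()].
#' @param z Positive frailty value.
#' @param x Numeric covariate (design) row, same length as `spec$beta`.
#' @param t Positive time(s).
#' @export
conditional_hazard <- function(spec, z, x, t) {
  stopifnot(inherits(spec, "frailty_spec"))
  if (any(z <= 0)) stop("frailty z must be strictly positive", call. = FALSE)
  if (length(x) != length(spec$beta))
    stop("covariate row length does not match beta", call. = FALSE)
  z * base_hazard(spec$baseline, t) * exp(sum(x * spec$beta))
}

#' Log-density of the mean-one gamma frailty
#'
#' Gamma with shape `1/theta` and rate `1/theta`: mean 1, variance `theta`.
#'
#' @param z Positive frailty value(s).
#' @param theta Frailty variance, `> 0`.
#' @export
frailty_log_density <- function(z, theta) {
  if (any(z <= 0)) stop("z must be strictly positive", call. = FALSE)
  if (theta <= 0) stop("theta must be strictly positive", call. = FALSE)
  stats::dgamma(z, shape = 1 / theta, rate = 1 / theta, log = TRUE)
}

#' Kendall's tau induced by gamma frailty
#'
#' Within-cluster rank correlation `theta / (theta + 2)`.
#'
#' @param theta Frailty variance, `>= 0`.
#' @export
kendalls_tau <- function(theta) {
  if (any(theta < 0)) stop("theta must be >= 0", call. = FALSE)
  theta / (theta + 2)
}

# Per-subject pieces reused by every likelihood: linear predictor, baseline
# log-hazard at the observed times, and cumulative hazard scaled by exp(lp).
loglik_pieces <- function(spec, ds) {
  stopifnot(inherits(spec, "frailty_spec"), inherits(ds, "survival_dataset"))
  if (length(spec$beta) != ncol(ds$X))
    stop("beta length does not match the dataset design matrix", call. = FALSE)
  lp <- if (length(spec$beta)) drop(ds$X %*% spec$beta) else numeric(ds$n)
  list(lp = lp,
       logh0 = base_loghaz(spec$baseline, ds$data$time),
       Hx = base_cumhaz(spec$baseline, ds$data$time) * exp(lp))
}

#' Complete-data log-likelihood
#'
#' Log-likelihood of the observed data given the (latent) cluster frailties:
#' \eqn{\sum_{ij} \delta_{ij} \log[z_i h_0(t_{ij}) e^{x'\beta}] - z_i
#' H_0(t_{ij}) e^{x'\beta}}.  Does not include the frailty density; see
#' [log_posterior()] for the full augmented target.
#'
#' @param spec A [frailty_spec()].
#' @param ds A [survival_dataset()].
#' @param frailties Named positive vector, one frailty per cluster (names =
#'   cluster labels).
#' @export
complete_data_loglik <- function(spec, ds, frailties) {
  pieces <- loglik_pieces(spec, ds)
  labs <- levels(ds$cluster)
  if (!setequal(names(frailties), labs))
    stop("frailties must cover exactly the dataset's clusters", call. = FALSE)
  z <- frailties[labs][ds$cluster_index]
  if (any(z <= 0)) stop("frailties must be strictly positive", call. = FALSE)
  ev <- ds$data$event
  sum(ev * (log(z) + pieces$logh0 + pieces$lp)) - sum(z * pieces$Hx)
}

# Stable evaluation of the per-cluster gamma-frailty marginal terms.
# d: integer event counts; A: summed covariate-scaled cumulative hazards.
# Returns sum over clusters of
#   -(1/th) log(1 + th A) + log Gamma(1/th + d) - log Gamma(1/th)
#   - d log(1/th + A).
marginal_cluster_terms <- function(d, A, theta) {
  if (theta < 1e-12) return(-sum(A))
  if (theta > 1e-4) {
    a <- 1 / theta
    sum(-a * log1p(theta * A) + lgamma(a + d) - lgamma(a) - d * log(a + A))
  } else {
    # tiny theta: lgamma differences cancel catastrophically; use the exact
    # finite product over the integer event count instead
    tot <- -sum(log1p(theta * A)) / theta
    for (i in seq_along(d)) {
      if (d[i] > 0) {
        k <- seq_len(d[i]) - 1
        tot <- tot + sum(log1p(k * theta) - log1p(theta * A[i]))
      }
    }
    tot
  }
}

#' Marginal (observed-data) log-likelihood
#'
#' The gamma frailty integrates out in closed form.  For cluster `i` with
#' `d_i` events and \eqn{A_i = \sum_j H_0(t_{ij}) e^{x_{ij}'\beta}},
#' \deqn{L_i = \Big[\prod_{j:\delta=1} h_0(t_{ij}) e^{x_{ij}'\beta}\Big]
#'   \frac{(1/\theta)^{1/\theta}\,\Gamma(1/\theta + d_i)}
#'        {\Gamma(1/\theta)\,(A_i + 1/\theta)^{1/\theta + d_i}}.}
#' The \eqn{\theta \to 0} limit (the independent parametric likelihood) is
#' taken analytically, so the frailty and no-frailty code paths join
#' continuously.
#'
#' @param spec A [frailty_spec()] (`theta = 0` gives the no-frailty
#'   likelihood).
#' @param ds A [survival_dataset()].
#' @export
marginal_loglik <- function(spec, ds) {
  pieces <- loglik_pieces(spec, ds)
  ev <- ds$data$event
  d <- as.vector(rowsum(ev, ds$cluster_index))
  A <- as.vector(rowsum(pieces$Hx, ds$cluster_index))
  sum(ev * (pieces$logh0 + pieces$lp)) +
    marginal_cluster_terms(d, A, spec$theta)
}

## ---- parameter transforms shared by the ML fitter and the MCMC sampler ----

# Positive parameters are optimized/sampled on the log scale; real-valued
# shape parameters (Gompertz theta, log-logistic theta, lognormal mu) stay
# on the identity scale.
baseline_tinfo <- function(family) {
  nm <- baseline_param_names(family)
  logscale <- switch(family,
    exponential = TRUE,
    weibull     = c(TRUE, TRUE),
    gompertz    = c(TRUE, FALSE),
    lognormal   = c(FALSE, TRUE),
    loglogistic = c(FALSE, TRUE))
  list(names = nm, log = logscale)
}

baseline_to_tpar <- function(spec) {
  info <- baseline_tinfo(spec$family)
  v <- unlist(spec$params[info$names])
  ifelse(info$log, log(v), v)
}

tpar_to_baseline <- function(family, tpar) {
  info <- baseline_tinfo(family)
  v <- ifelse(info$log, exp(tpar), tpar)
  do.call(baseline_spec, c(list(family = family), as.list(stats::setNames(v, info$names))))
}

# crude data-driven starting values on the transformed scale
baseline_start <- function(family, ds) {
  t <- ds$data$time; ev <- ds$data$event
  lam0 <- max(sum(ev), 0.5) / sum(t)
  km <- survival::survfit(survival::Surv(t, ev) ~ 1)
  keep <- km$n.event > 0 & km$surv > 1e-8 & km$surv < 1
  slope <- 1; inter <- log(lam0)
  if (sum(keep) >= 3) {
    # OLS of log cumulative hazard on log time: exact for Weibull, a sane
    # shape probe for the other families
    fit <- stats::lm.fit(cbind(1, log(km$time[keep])),
                         log(-log(km$surv[keep])))
    inter <- fit$coefficients[1]; slope <- max(fit$coefficients[2], 0.05)
  }
  mu <- mean(log(t)); sdl <- max(stats::sd(log(t)), 0.05)
  switch(family,
    exponential = log(lam0),
    weibull     = c(inter, log(slope)),
    gompertz    = c(log(lam0), 0),
    lognormal   = c(mu, log(sdl)),
    loglogistic = c(inter, log(slope)))
}

#' Fit a parametric (frailty) survival model by maximum likelihood
#'
#' Maximizes the closed-form marginal log-likelihood over the baseline
#' parameters, regression coefficients and (optionally) the frailty variance
#' `theta`, the latter kept nonnegative through a log transform.  Multi-start
#' quasi-Newton optimization (data-driven, null-model and perturbed starts);
#' standard errors from the numerically differentiated observed information
#' at the optimum, delta-method mapped back to the natural scale.
#'
#' @param ds A [survival_dataset()].
#' @param family Baseline family name (see [baseline_spec()]).
#' @param frailty Logical; include the gamma shared frailty?
#' @param nstarts Number of optimization starts (default 3).
#' @param start_jitter_sd SD of the Gaussian perturbation used for the extra
#'   starts.
#' @param seed Seed controlling the perturbed starts (fit is deterministic
#'   given it).
#' @return An object of class `gsf_mlfit` with elements `spec` (fitted
#'   [frailty_spec()]), `estimates`, `se`, `loglik`, `aic`, `bic`, `n_params`,
#'   `converged`, `boundary_theta`.
#' @export
fit_ml <- function(ds, family, frailty = TRUE, nstarts = 3,
                   start_jitter_sd = 0.3, seed = 1L) {
  stopifnot(inherits(ds, "survival_dataset"))
  if (sum(ds$data$event) < 1) stop("no events in the dataset", call. = FALSE)
  info <- baseline_tinfo(family)
  nb <- length(info$names)
  p <- ncol(ds$X)
  pnames <- c(info$names, colnames(ds$X), if (frailty) "theta")

  negll <- function(par) {
    bl <- try(tpar_to_baseline(family, par[seq_len(nb)]), silent = TRUE)
    if (inherits(bl, "try-error")) return(1e10)
    beta <- par[nb + seq_len(p)]
    theta <- if (frailty) exp(par[nb + p + 1]) else 0
    if (!is.finite(theta) || theta > 1e6) return(1e10)
    ll <- marginal_loglik(frailty_spec(bl, stats::setNames(beta, colnames(ds$X)),
                                       theta), ds)
    if (!is.finite(ll)) 1e10 else -ll
  }

  base0 <- baseline_start(family, ds)
  starts <- list(c(base0, rep(0, p), if (frailty) log(0.1)))
  # null start: exponential-equivalent shape, no covariate effects
  null0 <- base0
  if (family == "weibull") null0[2] <- 0
  if (family == "gompertz") null0[2] <- 0
  if (family == "loglogistic") null0[2] <- 0
  starts <- c(starts, list(c(null0, rep(0, p), if (frailty) log(0.5))))
  set.seed(seed)
  while (length(starts) < nstarts)
    starts <- c(starts, list(starts[[1]] +
      stats::rnorm(length(starts[[1]]), 0, start_jitter_sd)))

  fits <- lapply(starts, function(s)
    try(stats::optim(s, negll, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12)),
        silent = TRUE))
  fits <- Filter(function(f) !inherits(f, "try-error") && is.finite(f$value),
                 fits)
  if (!length(fits)) stop("all optimization starts failed", call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]

  par <- best$par
  bl <- tpar_to_baseline(family, par[seq_len(nb)])
  beta <- stats::setNames(par[nb + seq_len(p)], colnames(ds$X))
  theta <- if (frailty) exp(par[nb + p + 1]) else 0
  spec <- frailty_spec(bl, beta, theta)
  ll <- -best$value
  P <- length(par)

  # observed information on the transformed scale, delta method back
  H <- try(stats::optimHess(par, negll), silent = TRUE)
  se_nat <- rep(NA_real_, P)
  tse <- rep(NA_real_, P)
  tcov <- NULL
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error")) {
      tcov <- V
      vd <- diag(V)
      vd[vd < 0] <- NA
      tse <- sqrt(vd)
      jac <- c(ifelse(info$log, unlist(bl$params[info$names]), 1),
               rep(1, p), if (frailty) theta)
      se_nat <- tse * jac
    }
  }
  est <- c(unlist(bl$params[info$names]), beta, if (frailty) theta)
  names(est) <- pnames
  names(se_nat) <- pnames
  boundary <- frailty && theta < 1e-4
  if (boundary) se_nat["theta"] <- NA_real_

  structure(list(
    spec = spec, family = family, frailty = frailty,
    estimates = est, se = se_nat, loglik = ll,
    aic = -2 * ll + 2 * P, bic = -2 * ll + P * log(ds$n),
    n = ds$n, n_params = P,
    converged = best$convergence == 0,
    boundary_theta = boundary,
    tpar = par, tse = tse, tcov = tcov,
    data_fingerprint = dataset_fingerprint(ds)),
    class = "gsf_mlfit")
}

dataset_fingerprint <- function(ds) {
  c(n = ds$n, events = sum(ds$data$event),
    tsum = round(sum(ds$data$time), 9), r = ds$r)
}

#' @export
print.gsf_mlfit <- function(x, ...) {
  cat(sprintf("ML fit: %s baseline, %s\n", x$family,
              if (x$frailty) "gamma shared frailty" else "no frailty"))
  tab <- data.frame(estimate = x$estimates, se = x$se)
  print(round(tab, 5))
  cat(sprintf("logLik %.3f  AIC %.3f  BIC %.3f  (P = %d, n = %d)\n",
              x$loglik, x$aic, x$bic, x$n_params, x$n))
  if (!x$converged) cat("WARNING: optimizer did not report convergence\n")
  if (x$boundary_theta)
    cat("NOTE: theta on the boundary (< 1e-4); SE not reported\n")
  invisible(x)
}

#' Rank maximum-likelihood fits by AIC
#'
#' All fits must come from the same dataset.  Rows are sorted by AIC and the
#' minimum-AIC model flagged as best.
#'
#' @param results A list of [fit_ml()] results.
#' @return A data.frame with one row per model.
#' @export
compare_ml <- function(results) {
  stopifnot(length(results) >= 1, all(vapply(results, inherits, logical(1),
                                             "gsf_mlfit")))
  fps <- lapply(results, `[[`, "data_fingerprint")
  if (length(unique(vapply(fps, paste, character(1), collapse = "|"))) != 1)
    stop("fits come from different datasets", call. = FALSE)
  tab <- do.call(rbind, lapply(results, function(f)
    data.frame(family = f$family, frailty = f$frailty, loglik = f$loglik,
               n_params = f$n_params, aic = f$aic, bic = f$bic,
               converged = f$converged, stringsAsFactors = FALSE)))
  tab <- tab[order(tab$aic), , drop = FALSE]
  tab$best <- seq_len(nrow(tab)) == 1L
  rownames(tab) <- NULL
  tab
}

#' Convert Weibull PH coefficients to the AFT scale
#'
#' For the Weibull family the proportional-hazards and accelerated
#' failure-time parameterizations coincide up to `beta_AFT =
#' -beta_PH / gamma`.  Provided for comparison with AFT-reported software.
#'
#' @param beta_ph PH coefficient vector.
#' @param gamma Weibull shape.
#' @export
weibull_ph_to_aft <- function(beta_ph, gamma) {
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  -beta_ph / gamma
}
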