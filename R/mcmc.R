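#' Prior specification for Bayesian frailty models
#'
#' Vague proper priors: independent normal(0, `beta_var`) on every regression
#' coefficient and on real-valued baseline parameters; gamma(`baseline_shape`,
#' rate `baseline_rate`) on strictly positive baseline scale/shape parameters
#' (mean 1000, variance 1e6 at the defaults); and gamma(`frailty_prec_shape`,
#' rate `frailty_prec_rate`) on the frailty precision `1/theta` (an
#' inverse-gamma prior on the frailty variance itself).
#'
#' @param beta_var Normal prior variance for coefficients (default `1e5`).
#' @param baseline_shape,baseline_rate Gamma prior (shape, rate) for positive
#'   baseline parameters (defaults 1 and 0.001).
#' @param frailty_prec_shape,frailty_prec_rate Gamma prior (shape, rate) for
#'   the frailty precision (defaults 0.001 and 0.001).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(beta_var = 1e5, baseline_shape = 1,
                       baseline_rate = 0.001, frailty_prec_shape = 0.001,
                       frailty_prec_rate = 0.001) {
  vals <- c(beta_var, baseline_shape, baseline_rate, frailty_prec_shape,
            frailty_prec_rate)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all prior hyperparameters must be positive and finite",
         call. = FALSE)
  structure(list(beta_var = beta_var, baseline_shape = baseline_shape,
                 baseline_rate = baseline_rate,
                 frailty_prec_shape = frailty_prec_shape,
                 frailty_prec_rate = frailty_prec_rate),
            class = "prior_spec")
}

# log prior density of the model parameters on the natural scale
log_prior <- function(spec, priors, frailty = TRUE) {
  info <- baseline_tinfo(spec$baseline$family)
  lp <- 0
  for (i in seq_along(info$names)) {
    v <- spec$baseline$params[[info$names[i]]]
    lp <- lp + if (info$log[i])
      stats::dgamma(v, priors$baseline_shape, rate = priors$baseline_rate,
                    log = TRUE)
    else stats::dnorm(v, 0, sqrt(priors$beta_var), log = TRUE)
  }
  if (length(spec$beta))
    lp <- lp + sum(stats::dnorm(spec$beta, 0, sqrt(priors$beta_var),
                                log = TRUE))
  if (frailty) {
    if (spec$theta <= 0) return(-Inf)
    # precision 1/theta ~ gamma; change of variables to theta
    lp <- lp + stats::dgamma(1 / spec$theta, priors$frailty_prec_shape,
                             rate = priors$frailty_prec_rate, log = TRUE) -
      2 * log(spec$theta)
  }
  lp
}

#' Log posterior density of the augmented frailty model
#'
#' Complete-data log-likelihood plus the frailty log-densities plus the log
#' priors, up to an additive constant.  States violating a positivity
#' constraint return `-Inf` (a rejected state), not an error.
#'
#' @param spec A [frailty_spec()] with `theta > 0`.
#' @param frailties Named positive frailty vector (one per cluster).
#' @param ds A [survival_dataset()].
#' @param priors A [prior_spec()].
#' @export
log_posterior <- function(spec, frailties, ds, priors = prior_spec()) {
  if (spec$theta <= 0 || any(frailties <= 0) ||
      any(!is.finite(unlist(spec$baseline$params))))
    return(-Inf)
  pos <- baseline_tinfo(spec$baseline$family)
  pv <- unlist(spec$baseline$params)[pos$log]
  if (any(pv <= 0)) return(-Inf)
  complete_data_loglik(spec, ds, frailties) +
    sum(frailty_log_density(frailties[levels(ds$cluster)], spec$theta)) +
    log_prior(spec, priors, frailty = TRUE)
}

#' Full conditional of a cluster frailty
#'
#' Under the augmented model the frailty of a cluster with `d` events and
#' covariate-scaled cumulative hazard sum `A` is conjugate:
#' `z | rest ~ Gamma(1/theta + d, rate 1/theta + A)`.  A cluster contributing
#' no subjects (`d = A = 0`) reduces to the prior `Gamma(1/theta, 1/theta)`.
#'
#' @param theta Frailty variance (> 0).
#' @param d Event count(s).
#' @param A Summed `H0(t) exp(x'beta)` per cluster.
#' @return List with `shape` and `rate` vectors.
#' @export
frailty_conditional <- function(theta, d, A) {
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  list(shape = 1 / theta + d, rate = 1 / theta + A)
}

# per-cluster sufficient statistics for the frailty conditional
cluster_stats <- function(spec, ds) {
  pieces <- loglik_pieces(spec, ds)
  list(d = as.vector(rowsum(ds$data$event, ds$cluster_index)),
       A = as.vector(rowsum(pieces$Hx, ds$cluster_index)))
}

#' Gibbs update of the cluster frailties
#'
#' Exact draw from the gamma full conditional of every cluster frailty given
#' the current model parameters.  Uses the R random number stream; wrap in
#' [set.seed()] for reproducibility.
#'
#' @param spec A [frailty_spec()] with `theta > 0`.
#' @param ds A [survival_dataset()].
#' @return Named positive frailty vector, one entry per cluster.
#' @export
gibbs_update_frailties <- function(spec, ds) {
  if (spec$theta <= 0) stop("theta must be > 0", call. = FALSE)
  st <- cluster_stats(spec, ds)
  fc <- frailty_conditional(spec$theta, st$d, st$A)
  stats::setNames(stats::rgamma(ds$r, shape = fc$shape, rate = fc$rate),
                  levels(ds$cluster))
}

# Generic random-walk Metropolis step on an unconstrained vector.
# logtarget(x) returns the log target density (may be -Inf).
# A zero proposal scale leaves the corresponding coordinate unchanged;
# all-zero scales always accept the unchanged state.
mh_step <- function(logtarget, x, scales, lt_x = NULL) {
  if (is.null(lt_x)) lt_x <- logtarget(x)
  prop <- x + scales * stats::rnorm(length(x))
  lt_p <- logtarget(prop)
  if (is.finite(lt_p) && log(stats::runif(1)) < lt_p - lt_x)
    list(x = prop, lt = lt_p, accept = TRUE)
  else
    list(x = x, lt = lt_x, accept = FALSE)
}

# (de)construct the unconstrained parameter vector of one MH block
block_to_u <- function(spec, block) {
  switch(block,
    baseline = baseline_to_tpar(spec$baseline),
    beta     = unname(spec$beta),
    theta    = log(spec$theta))
}

u_to_spec <- function(spec, block, u) {
  switch(block,
    baseline = frailty_spec(tpar_to_baseline(spec$baseline$family, u),
                            spec$beta, spec$theta),
    beta     = frailty_spec(spec$baseline,
                            stats::setNames(u, names(spec$beta)), spec$theta),
    theta    = frailty_spec(spec$baseline, spec$beta, exp(u)))
}

# log Jacobian of the natural -> unconstrained map for one block
block_log_jacobian <- function(spec, block, u) {
  switch(block,
    baseline = sum(u[baseline_tinfo(spec$baseline$family)$log]),
    beta     = 0,
    theta    = u)
}

#' One random-walk Metropolis update of a parameter block
#'
#' Blocks: `"beta"` (joint update of all coefficients, identity scale),
#' `"baseline"` (baseline parameters, positive ones on the log scale) and
#' `"theta"` (log frailty variance).  The proposal is a Gaussian random walk
#' on the unconstrained scale; acceptance uses the posterior ratio times the
#' change-of-variables Jacobian, so detailed balance holds for the natural
#' parameters.
#'
#' @param spec Current [frailty_spec()].
#' @param frailties Current named frailty vector.
#' @param ds A [survival_dataset()].
#' @param priors A [prior_spec()].
#' @param block One of `"beta"`, `"baseline"`, `"theta"`.
#' @param scales Proposal standard deviation(s) for the block (0 = degenerate
#'   proposal that always accepts the unchanged state).
#' @return List with the updated `spec` and an `accept` flag.
#' @export
metropolis_update_block <- function(spec, frailties, ds, priors, block,
                                    scales) {
  block <- match.arg(block, c("beta", "baseline", "theta"))
  lt <- function(u) {
    sp <- try(u_to_spec(spec, block, u), silent = TRUE)
    if (inherits(sp, "try-error")) return(-Inf)
    log_posterior(sp, frailties, ds, priors) +
      block_log_jacobian(spec, block, u)
  }
  u <- block_to_u(spec, block)
  step <- mh_step(lt, u, rep_len(scales, length(u)))
  list(spec = u_to_spec(spec, block, step$x), accept = step$accept)
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' Samples the posterior of a parametric (optionally gamma shared-frailty)
#' proportional-hazards model.  Cluster frailties are drawn exactly from
#' their conjugate gamma full conditionals; the coefficient block, the
#' baseline-parameter block and log `theta` use adaptive random-walk
#' Metropolis proposals against the marginal (frailty-integrated) posterior,
#' which removes the weakly identified random walk between the frailty level
#' and the baseline scale.  Proposal scales adapt only during burn-in
#' (targeting `target_accept`), so the post-burn-in kernel is fixed and
#' valid.  Chains start from the maximum-likelihood estimate (chain 1) and
#' overdispersed perturbations of it (later chains).
#'
#' @param ds A [survival_dataset()].
#' @param family Baseline family name.
#' @param frailty Logical; include the gamma shared frailty?
#' @param priors A [prior_spec()].
#' @param iters Kept iterations per chain (after burn-in).
#' @param burnin Burn-in iterations discarded per chain.
#' @param chains Number of chains (default 2).
#' @param thin Thinning interval.
#' @param seed Integer seed; the run is bitwise reproducible given it.
#' @param init Optional [fit_ml()] result to reuse for starts/scales.
#' @param adapt Adapt proposal scales during burn-in?
#' @param target_accept Acceptance target for adaptation (default 0.3, inside
#'   the 0.25-0.40 band the proposals aim for).
#' @param progress_every Emit a progress message every so many iterations
#'   (0 = silent).
#' @return An object of class `gsf_chains`: per-chain sample matrices on the
#'   natural scale (baseline parameters, coefficients, `theta`, cluster
#'   frailties), log-posterior traces, acceptance rates, and run metadata.
#' @export
run_mcmc <- function(ds, family, frailty = TRUE, priors = prior_spec(),
                     iters = 20000, burnin = 1000, chains = 2, thin = 1,
                     seed = 1L, init = NULL, adapt = TRUE,
                     target_accept = 0.3, progress_every = 0) {
  stopifnot(inherits(ds, "survival_dataset"))
  if (iters < 1 || burnin < 0 || thin < 1 || chains < 1)
    stop("invalid MCMC run lengths", call. = FALSE)
  info <- baseline_tinfo(family)
  nb <- length(info$names)
  p <- ncol(ds$X)
  labs <- levels(ds$cluster)
  r <- ds$r
  t <- ds$data$time; ev <- ds$data$event; X <- ds$X; ci <- ds$cluster_index
  d <- as.vector(rowsum(ev, ci))

  ml <- if (inherits(init, "gsf_mlfit")) init
        else fit_ml(ds, family, frailty = frailty, seed = seed)
  if (ml$frailty != frailty || ml$family != family)
    stop("init fit does not match the requested model", call. = FALSE)
  tpar <- ml$tpar
  tse <- ml$tse
  tse[!is.finite(tse) | tse <= 0] <- 0.1

  i_base <- seq_len(nb)
  i_beta <- nb + seq_len(p)
  i_lth <- if (frailty) nb + p + 1L

  pnames <- c(info$names, colnames(X),
              if (frailty) c("theta", paste0("z.", labs)))
  npar <- length(pnames)
  blocks <- c("baseline", if (p > 0) "beta", if (frailty) "theta")

  samples <- vector("list", chains)
  lp_trace <- vector("list", chains)
  acc_rates <- vector("list", chains)
  total <- burnin + iters * thin

  sqbv <- sqrt(priors$beta_var)

  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed + 7919L * (ch - 1L)))
    u <- tpar
    if (ch > 1) u <- u + stats::rnorm(length(u), 0, pmin(2 * tse, 0.5))
    ub <- u[i_base]; beta <- u[i_beta]
    ltheta <- if (frailty) u[i_lth]
    theta <- if (frailty) exp(ltheta) else 0
    z <- rep(1, r)

    # block proposal shapes from the ML covariance (Cholesky); the scalar
    # `scales` multipliers are what burn-in adaptation tunes
    chol_of <- function(ii) {
      fallback <- diag(tse[ii], length(ii))
      if (is.null(ml$tcov)) return(fallback)
      L <- try(chol(ml$tcov[ii, ii, drop = FALSE]), silent = TRUE)
      if (inherits(L, "try-error") || any(!is.finite(L))) fallback else L
    }
    shapes <- list(baseline = chol_of(i_base),
                   beta = if (p > 0) chol_of(i_beta))
    scales <- list(
      baseline = 2.4 / sqrt(nb),
      beta = if (p > 0) 2.4 / sqrt(p),
      theta = if (frailty) max(2.4 * tse[i_lth], 0.05))

    # cached O(n) pieces; the Metropolis blocks target the marginal
    # (frailty-integrated) posterior, so the sampler does not random-walk
    # along the weakly identified frailty-level/baseline-scale direction
    bl <- tpar_to_baseline(family, ub)
    logh0 <- base_loghaz(bl, t); H0 <- base_cumhaz(bl, t)
    lp_vec <- if (p > 0) drop(X %*% beta) else numeric(ds$n)
    explp <- exp(lp_vec)
    evterm <- sum(ev * (logh0 + lp_vec))
    A <- as.vector(rowsum(H0 * explp, ci))
    mct <- function(A_, th_) marginal_cluster_terms(d, A_, th_)

    base_logprior <- function(ub_) {
      v <- ifelse(info$log, exp(ub_), ub_)
      lp_ <- 0
      for (i in seq_len(nb))
        lp_ <- lp_ + if (info$log[i])
          stats::dgamma(v[i], priors$baseline_shape,
                        rate = priors$baseline_rate, log = TRUE) + ub_[i]
        else stats::dnorm(v[i], 0, sqbv, log = TRUE)
      lp_
    }
    theta_logprior <- function(lth) {
      th <- exp(lth)
      stats::dgamma(1 / th, priors$frailty_prec_shape,
                    rate = priors$frailty_prec_rate, log = TRUE) -
        2 * lth + lth
    }

    kept <- matrix(NA_real_, iters, npar, dimnames = list(NULL, pnames))
    lps <- numeric(iters)
    acc <- stats::setNames(numeric(length(blocks)), blocks)
    accw <- acc
    k <- 0L

    mterm <- if (frailty) mct(A, theta) else -sum(A)

    for (it in seq_len(total)) {
      ## baseline block
      prop <- ub + scales$baseline *
        drop(crossprod(shapes$baseline, stats::rnorm(nb)))
      blp <- try(tpar_to_baseline(family, prop), silent = TRUE)
      if (!inherits(blp, "try-error")) {
        logh0p <- base_loghaz(blp, t); H0p <- base_cumhaz(blp, t)
        evtermp <- sum(ev * (logh0p + lp_vec))
        Ap <- as.vector(rowsum(H0p * explp, ci))
        mtermp <- if (frailty) mct(Ap, theta) else -sum(Ap)
        dl <- (evtermp + mtermp) - (evterm + mterm) +
          base_logprior(prop) - base_logprior(ub)
        if (is.finite(dl) && log(stats::runif(1)) < dl) {
          ub <- prop; logh0 <- logh0p; H0 <- H0p
          evterm <- evtermp; A <- Ap; mterm <- mtermp
          acc["baseline"] <- acc["baseline"] + 1
          accw["baseline"] <- accw["baseline"] + 1
        }
      }

      ## beta block
      if (p > 0) {
        prop <- beta + scales$beta *
          drop(crossprod(shapes$beta, stats::rnorm(p)))
        lp_p <- drop(X %*% prop)
        explpp <- exp(lp_p)
        evtermp <- sum(ev * (logh0 + lp_p))
        Ap <- as.vector(rowsum(H0 * explpp, ci))
        mtermp <- if (frailty) mct(Ap, theta) else -sum(Ap)
        dl <- (evtermp + mtermp) - (evterm + mterm) +
          sum(stats::dnorm(prop, 0, sqbv, log = TRUE)) -
          sum(stats::dnorm(beta, 0, sqbv, log = TRUE))
        if (is.finite(dl) && log(stats::runif(1)) < dl) {
          beta <- prop; lp_vec <- lp_p; explp <- explpp
          evterm <- evtermp; A <- Ap; mterm <- mtermp
          acc["beta"] <- acc["beta"] + 1
          accw["beta"] <- accw["beta"] + 1
        }
      }

      if (frailty) {
        ## theta block, also against the marginal posterior
        prop <- ltheta + scales$theta * stats::rnorm(1)
        thp <- exp(prop)
        mtermp <- mct(A, thp)
        dl <- (mtermp - mterm) +
          theta_logprior(prop) - theta_logprior(ltheta)
        if (is.finite(dl) && log(stats::runif(1)) < dl) {
          ltheta <- prop; theta <- thp; mterm <- mtermp
          acc["theta"] <- acc["theta"] + 1
          accw["theta"] <- accw["theta"] + 1
        }

        ## exact draw of the frailties from their gamma full conditional
        z <- stats::rgamma(r, shape = 1 / theta + d, rate = 1 / theta + A)
      }

      ## burn-in adaptation
      if (adapt && it <= burnin && it %% 50L == 0L) {
        for (b in blocks) {
          rate <- accw[b] / 50
          scales[[b]] <- scales[[b]] * exp(0.66 * (rate - target_accept))
          accw[b] <- 0
        }
      }

      if (it > burnin && (it - burnin) %% thin == 0L) {
        k <- k + 1L
        v <- ifelse(info$log, exp(ub), ub)
        kept[k, ] <- c(v, beta, if (frailty) c(theta, z))
        ll <- if (frailty) sum(d * log(z)) + evterm - sum(z * A)
              else evterm - sum(A)
        lps[k] <- ll +
          (if (frailty)
             sum(stats::dgamma(z, 1 / theta, rate = 1 / theta, log = TRUE)) +
             theta_logprior(ltheta) - ltheta
           else 0) +
          base_logprior(ub) - sum(ifelse(info$log, ub, 0)) +
          (if (p > 0) sum(stats::dnorm(beta, 0, sqbv, log = TRUE)) else 0)
      }
      if (progress_every > 0 && it %% progress_every == 0L)
        message(sprintf("chain %d: iteration %d/%d", ch, it, total))
    }
    samples[[ch]] <- kept
    lp_trace[[ch]] <- lps
    acc_rates[[ch]] <- acc / total
  }

  structure(list(samples = samples, log_posterior = lp_trace,
                 acceptance = acc_rates, family = family, frailty = frailty,
                 parameters = pnames,
                 monitor = c(info$names, colnames(X), if (frailty) "theta"),
                 iters = iters, burnin = burnin, thin = thin,
                 chains = chains, seed = seed, priors = priors,
                 cluster_labels = labs, ml_fit = ml),
            class = "gsf_chains")
}

#' @export
print.gsf_chains <- function(x, ...) {
  cat(sprintf("MCMC run: %s baseline, %s; %d chain(s) x %d kept (burn-in %d, thin %d)\n",
              x$family,
              if (x$frailty) "gamma shared frailty" else "no frailty",
              x$chains, x$iters, x$burnin, x$thin))
  for (ch in seq_len(x$chains))
    cat(sprintf("  chain %d acceptance: %s\n", ch,
                paste(sprintf("%s %.2f", names(x$acceptance[[ch]]),
                              x$acceptance[[ch]]), collapse = ", ")))
  invisible(x)
}
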