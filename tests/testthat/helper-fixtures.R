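# Shared fixtures and independent oracles, built in code at test time.

# quick dataset from parallel vectors (single binary covariate optional)
toy_dataset <- function(time, event, cluster = "c1", group = NULL) {
  df <- data.frame(time = time, event = event, cluster = cluster)
  cb <- NULL
  if (!is.null(group)) {
    df$group <- group
    cb <- codebook(list(group = sort(unique(as.character(group)))))
  }
  survival_dataset(df, cb)
}

# random small clustered dataset with one binary covariate
random_small_dataset <- function(n = 40, r = 4) {
  cl <- sample(paste0("c", seq_len(r)), n, replace = TRUE)
  # make sure every cluster label appears
  cl[seq_len(r)] <- paste0("c", seq_len(r))
  toy_dataset(time = stats::runif(n, 0.3, 3),
              event = stats::rbinom(n, 1, 0.7),
              cluster = cl,
              group = sample(c("a", "b"), n, replace = TRUE))
}

# Independent oracle: marginal log-likelihood by adaptive quadrature of the
# frailty integral, cluster by cluster (never calls marginal_loglik).
quadrature_marginal_ll <- function(spec, ds) {
  th <- spec$theta
  lp <- if (length(spec$beta)) drop(ds$X %*% spec$beta) else numeric(ds$n)
  logh0 <- base_loghaz(spec$baseline, ds$data$time)
  Hx <- base_cumhaz(spec$baseline, ds$data$time) * exp(lp)
  ev <- ds$data$event
  tot <- sum(ev * (logh0 + lp))
  for (i in seq_len(ds$r)) {
    sel <- ds$cluster_index == i
    d <- sum(ev[sel]); A <- sum(Hx[sel])
    # peak-normalized integrand split at the mode (mean when the integrand
    # is boundary-singular), finite upper bracket: keeps the quadrature at
    # full relative precision even when z^d e^{-zA} is sharply peaked
    a <- 1 / th
    logf <- function(z) d * log(z) - z * A +
      stats::dgamma(z, a, rate = a, log = TRUE)
    sh <- d + a; rt <- A + a
    hi <- stats::qgamma(1e-15, sh, rate = rt, lower.tail = FALSE)
    split <- if (sh > 1) (sh - 1) / rt else sh / rt
    lmax <- logf(split)
    f <- function(z) exp(logf(z) - lmax)
    val <- stats::integrate(f, 0, split, rel.tol = 1e-12)$value +
      stats::integrate(f, split, hi, rel.tol = 1e-12)$value
    tot <- tot + lmax + log(val)
  }
  tot
}

# Independent oracle: slow per-subject loop for the complete-data likelihood.
loop_complete_ll <- function(spec, ds, frailties) {
  tot <- 0
  for (j in seq_len(ds$n)) {
    z <- frailties[[as.character(ds$data$cluster[j])]]
    x <- ds$X[j, ]
    h <- z * base_hazard(spec$baseline, ds$data$time[j]) *
      exp(sum(x * spec$beta))
    H <- z * base_cumhaz(spec$baseline, ds$data$time[j]) *
      exp(sum(x * spec$beta))
    tot <- tot + ds$data$event[j] * log(h) - H
  }
  tot
}

# Independent oracle: K=2 log-rank by explicit observed-minus-expected
# tabulation over distinct event times (hypergeometric variance).
logrank_oracle_2group <- function(time, event, group) {
  g <- as.integer(factor(group))
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tt in ts) {
    at <- time >= tt
    n1 <- sum(at & g == 1); n <- sum(at)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g == 1)
    O <- O + d1
    E <- E + n1 * d / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# dataset whose per-region event/censored counts equal the reference survey
# margins (times are arbitrary; only the bookkeeping matters)
region_margin_dataset <- function() {
  tab <- reference_region_table()
  rows <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    data.frame(
      time = c(rep(20, tab$events[i]), rep(25, tab$censored[i])),
      event = c(rep(1, tab$events[i]), rep(0, tab$censored[i])),
      cluster = tab$region[i], stringsAsFactors = FALSE)
  }))
  survival_dataset(rows, NULL)
}

# minimal gsf_chains-shaped object for summary/diagnostic unit tests
fake_chains <- function(samples_list, burnin = 0) {
  pn <- colnames(samples_list[[1]])
  structure(list(samples = samples_list,
                 log_posterior = lapply(samples_list, function(m)
                   rep(0, nrow(m))),
                 acceptance = lapply(samples_list, function(m) c(all = 1)),
                 family = "weibull", frailty = FALSE,
                 parameters = pn, monitor = pn,
                 iters = nrow(samples_list[[1]]), burnin = burnin, thin = 1,
                 chains = length(samples_list), seed = 1,
                 priors = prior_spec(), cluster_labels = character(0),
                 ml_fit = NULL),
            class = "gsf_chains")
}

# small 3-covariate scenario used by several MCMC tests; published-regime
# truth (Weibull shape 6.1, theta 0.95) but a reduced covariate set
small_scenario <- function(n = 800, theta = 0.95, seed = 7) {
  scenario_spec(
    n = n,
    marginals = list(residence = c(urban = 2077, rural = 6733),
                     media = c(no = 6280, yes = 2530),
                     contraceptive = c(yes = 4459, no = 4351)),
    beta = c("residence.rural" = 0.2112, "media.yes" = -0.1168,
             "contraceptive.no" = 0.1134),
    theta = theta, seed = seed)
}
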