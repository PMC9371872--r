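test_that("log posterior equals the sum of its components", {
  set.seed(9)
  ds <- random_small_dataset(20, 3)
  sp <- frailty_spec(baseline_spec("weibull", lambda = 0.5, gamma = 1.5),
                     c(group.b = 0.4), theta = 0.9)
  z <- stats::setNames(c(0.8, 1.1, 1.4), levels(ds$cluster))
  pr <- prior_spec()
  expected <- complete_data_loglik(sp, ds, z) +
    sum(frailty_log_density(z, 0.9)) +
    stats::dgamma(0.5, 1, rate = 0.001, log = TRUE) +
    stats::dgamma(1.5, 1, rate = 0.001, log = TRUE) +
    stats::dnorm(0.4, 0, sqrt(1e5), log = TRUE) +
    stats::dgamma(1 / 0.9, 0.001, rate = 0.001, log = TRUE) - 2 * log(0.9)
  expect_equal(log_posterior(sp, z, ds, pr), expected, tolerance = 1e-10)

  # in the flat-prior limit, differences reduce to likelihood differences
  pr_flat <- prior_spec(beta_var = 1e12)
  sp2 <- frailty_spec(sp$baseline, c(group.b = -0.2), theta = 0.9)
  expect_equal(
    log_posterior(sp, z, ds, pr_flat) - log_posterior(sp2, z, ds, pr_flat),
    complete_data_loglik(sp, ds, z) - complete_data_loglik(sp2, ds, z),
    tolerance = 1e-6)

  # nonpositive frailty variance is a rejected state, not an exception
  sp0 <- frailty_spec(sp$baseline, sp$beta, theta = 0)
  expect_identical(log_posterior(sp0, z, ds, pr), -Inf)
  expect_identical(log_posterior(sp, stats::setNames(c(-1, 1, 1), names(z)),
                                 ds, pr), -Inf)
})

test_that("frailty full conditional is the conjugate gamma", {
  # empty cluster: the prior itself
  fc <- frailty_conditional(0.5, 0, 0)
  expect_equal(fc$shape, 2)
  expect_equal(fc$rate, 2)

  # long-run mean at (theta = 1, d = 2, A = 3) is 3/4
  set.seed(33)
  fc <- frailty_conditional(1, 2, 3)
  z <- stats::rgamma(1e5, fc$shape, rate = fc$rate)
  expect_lt(abs(mean(z) - 0.75), 3 * stats::sd(z) / sqrt(length(z)))
  ks <- stats::ks.test(z, stats::pgamma, shape = 3, rate = 4)
  expect_gt(ks$p.value, 0.01)

  # grid-normalized brute-force conditional density matches the analytic one
  set.seed(34)
  ds <- random_small_dataset(30, 3)
  sp <- frailty_spec(baseline_spec("weibull", lambda = 0.4, gamma = 1.3),
                     c(group.b = 0.2), theta = 0.7)
  st <- gsfrailty:::cluster_stats(sp, ds)
  zg <- seq(0.001, 8, length.out = 4000)
  dz <- zg[2] - zg[1]
  for (i in seq_len(ds$r)) {
    un <- zg^st$d[i] * exp(-zg * st$A[i]) *
      exp(frailty_log_density(zg, 0.7))
    un <- un / sum(un * dz)
    an <- stats::dgamma(zg, 1 / 0.7 + st$d[i], rate = 1 / 0.7 + st$A[i])
    expect_lt(sum(abs(un - an)) * dz, 1e-3)
  }

  # gibbs_update_frailties draws from exactly that conditional
  set.seed(35)
  z1 <- gibbs_update_frailties(sp, ds)
  set.seed(35)
  z2 <- stats::rgamma(ds$r, 1 / 0.7 + st$d, rate = 1 / 0.7 + st$A)
  expect_equal(unname(z1), z2)
})

test_that("the Metropolis kernel has the right invariant law on a normal toy", {
  # target: N(2, 1.5^2); chain moments must match within Monte Carlo error
  set.seed(55)
  lt <- function(x) stats::dnorm(x, 2, 1.5, log = TRUE)
  x <- 0; out <- numeric(2e4); acc <- 0
  for (i in seq_along(out)) {
    st <- gsfrailty:::mh_step(lt, x, 2.5)
    x <- st$x; out[i] <- x; acc <- acc + st$accept
  }
  ess <- 2e4 / 10  # conservative for a well-scaled RW
  expect_lt(abs(mean(out) - 2), 3 * 1.5 / sqrt(ess))
  expect_lt(abs(stats::sd(out) - 1.5), 0.15)
  expect_gt(acc / 2e4, 0.15)
  expect_lt(acc / 2e4, 0.6)

  # degenerate proposal always accepts the unchanged state
  st <- gsfrailty:::mh_step(lt, 1.23, 0)
  expect_true(st$accept)
  expect_equal(st$x, 1.23)
})

test_that("block updates preserve constraints and handle degenerate scales", {
  set.seed(66)
  ds <- random_small_dataset(25, 3)
  sp <- frailty_spec(baseline_spec("weibull", lambda = 0.4, gamma = 1.3),
                     c(group.b = 0.1), theta = 0.6)
  z <- stats::setNames(rep(1, ds$r), levels(ds$cluster))
  pr <- prior_spec()
  for (bl in c("beta", "baseline", "theta")) {
    up <- metropolis_update_block(sp, z, ds, pr, bl, 0)
    expect_true(up$accept)
    expect_equal(up$spec[c("beta", "theta")], sp[c("beta", "theta")])
    up2 <- metropolis_update_block(sp, z, ds, pr, bl, 0.3)
    expect_gt(up2$spec$theta, 0)
    expect_true(all(unlist(up2$spec$baseline$params[
      c("lambda", "gamma")]) > 0))
  }
})

test_that("sampler runs are reproducible and recover generating parameters", {
  set.seed(1)
  g <- generate_dataset(small_scenario(n = 2000, theta = 0.95, seed = 19))
  ml <- fit_ml(g$dataset, "weibull", frailty = TRUE, seed = 1)
  ch <- run_mcmc(g$dataset, "weibull", iters = 1500, burnin = 500,
                 chains = 2, seed = 23, init = ml)
  ch2 <- run_mcmc(g$dataset, "weibull", iters = 1500, burnin = 500,
                  chains = 2, seed = 23, init = ml)
  expect_identical(ch$samples, ch2$samples)

  sm <- summarize_posterior(ch)
  truth <- c(lambda = exp(-17.75), gamma = 6.1,
             "residence.rural" = 0.2112, "media.yes" = -0.1168,
             "contraceptive.no" = 0.1134, theta = 0.95)
  for (nm in names(truth)) {
    row <- sm[sm$parameter == nm, ]
    expect_lt(abs(row$mean - truth[[nm]]), 3 * row$sd)
  }
  # acceptance rates land in the band the proposals are tuned for
  for (a in ch$acceptance) expect_true(all(a > 0.15 & a < 0.5))
})

test_that("a constant covariate column leaves its coefficient prior-dominated", {
  set.seed(77)
  sc <- small_scenario(n = 500, seed = 77)
  g <- generate_dataset(sc)
  df <- g$dataset$data
  df$null_cov <- "a"
  df$null_cov[1] <- "a"  # constant in the data
  cb <- codebook(c(sc$codebook$levels, list(null_cov = c("a", "b"))))
  # category b never occurs: its design column is all zero
  ds <- survival_dataset(df, cb)
  ch <- run_mcmc(ds, "weibull", iters = 800, burnin = 300, chains = 2,
                 seed = 3)
  row <- summarize_posterior(ch)
  row <- row[row$parameter == "null_cov.b", ]
  expect_gt(row$upper, 0)
  expect_lt(row$lower, 0)
})

test_that("posterior summaries behave on degenerate and iid pseudo-chains", {
  cn <- matrix(5, 1000, 1, dimnames = list(NULL, "p"))
  sm <- summarize_posterior(fake_chains(list(cn)))
  expect_equal(sm$sd, 0)
  expect_equal(sm$mc_error, 0)
  expect_equal(sm$lower, 5)
  expect_equal(sm$upper, 5)
  expect_true(sm$mc_error_ok)

  set.seed(41)
  chains <- lapply(1:2, function(i)
    matrix(stats::rnorm(21000), ncol = 1, dimnames = list(NULL, "p")))
  sm <- summarize_posterior(fake_chains(chains))
  expect_lt(abs(sm$mean), 3 / sqrt(42000))
  # iid chain: batch means reduce to sd/sqrt(n)
  expect_equal(sm$mc_error, sm$sd / sqrt(42000), tolerance = 0.25)
  expect_true(sm$mc_error_ok)
  expect_equal(sm$sample, 42000)
})

test_that("DIC reduces to the plug-in deviance for a collapsed chain", {
  set.seed(50)
  g <- generate_dataset(small_scenario(n = 200, seed = 50))
  ds <- g$dataset
  draw <- c(lambda = exp(-17), gamma = 5.5, "residence.rural" = 0.2,
            "media.yes" = -0.1, "contraceptive.no" = 0.1)
  m <- matrix(rep(draw, each = 50), nrow = 50,
              dimnames = list(NULL, names(draw)))
  fc <- fake_chains(list(m))
  d <- compute_dic(fc, ds)
  expect_equal(d$pD, 0, tolerance = 1e-10)
  expect_equal(d$DIC, d$Dhat, tolerance = 1e-10)
  expect_equal(d$Dbar, -2 * marginal_loglik(frailty_spec(
    baseline_spec("weibull", lambda = draw[["lambda"]],
                  gamma = draw[["gamma"]]),
    draw[3:5], 0), ds), tolerance = 1e-8)
})

test_that("posterior spread shrinks roughly as one over root n", {
  t0 <- Sys.time()
  g1 <- generate_dataset(small_scenario(n = 700, seed = 61))
  g2 <- generate_dataset(small_scenario(n = 2800, seed = 62))
  ch1 <- run_mcmc(g1$dataset, "weibull", iters = 1200, burnin = 400,
                  chains = 1, seed = 9)
  ch2 <- run_mcmc(g2$dataset, "weibull", iters = 1200, burnin = 400,
                  chains = 1, seed = 9)
  s1 <- summarize_posterior(ch1); s2 <- summarize_posterior(ch2)
  for (nm in c("residence.rural", "media.yes", "contraceptive.no")) {
    ratio <- s1$sd[s1$parameter == nm] / s2$sd[s2$parameter == nm]
    expect_gt(ratio, 2 * 0.7)   # within ~30% of the root-4 = 2 prediction
    expect_lt(ratio, 2 * 1.3)
  }
})

test_that("BGR interval diagnostic separates converged from divergent chains", {
  set.seed(71)
  x <- stats::rnorm(5000)
  # duplicated chains: exactly one
  b <- bgr_diagnostic(list(x, x))
  expect_identical(b$psrf, 1)
  expect_true(all(b$series$ratio == 1))
  # independent chains from the same law: close to one
  b2 <- bgr_diagnostic(list(stats::rnorm(1e4), stats::rnorm(1e4)))
  expect_lt(b2$psrf, 1.05)
  # chains centred 10 apart: far above 1.5
  b3 <- bgr_diagnostic(list(stats::rnorm(4000), stats::rnorm(4000, 10)))
  expect_gt(b3$psrf, 1.5)
  expect_error(bgr_diagnostic(list(x)), "two chains")
})

test_that("convergence plot files are written and non-empty", {
  set.seed(81)
  g <- generate_dataset(small_scenario(n = 250, seed = 81))
  ch <- run_mcmc(g$dataset, "weibull", iters = 300, burnin = 150,
                 chains = 2, seed = 4)
  dir <- withr::local_tempdir()
  files <- convergence_plots(ch, dir, params = c("gamma", "theta"))
  expect_length(files, 6)
  expect_true(all(file.exists(files)))
  expect_true(all(file.size(files) > 0))
})

test_that("subject order does not change posterior conclusions", {
  set.seed(91)
  g <- generate_dataset(small_scenario(n = 600, seed = 91))
  ds <- g$dataset
  perm <- sample(ds$n)
  df2 <- ds$data[perm, ]
  # keep the cluster level order identical so only row order changes
  df2 <- df2[order(match(df2$cluster, levels(ds$cluster))), ]
  ds2 <- survival_dataset(df2, ds$codebook)
  ch1 <- run_mcmc(ds, "weibull", iters = 1000, burnin = 400, chains = 1,
                  seed = 13)
  ch2 <- run_mcmc(ds2, "weibull", iters = 1000, burnin = 400, chains = 1,
                  seed = 13)
  s1 <- summarize_posterior(ch1); s2 <- summarize_posterior(ch2)
  for (nm in s1$parameter) {
    i <- match(nm, s2$parameter)
    tol <- 4 * sqrt(s1$mc_error[s1$parameter == nm]^2 + s2$mc_error[i]^2) +
      1e-12
    expect_lt(abs(s1$mean[s1$parameter == nm] - s2$mean[i]),
              max(tol, 0.2 * s1$sd[s1$parameter == nm]))
  }
})
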