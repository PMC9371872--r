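# Default synthetic-data structure: 11 regional clusters with the relative
# sizes, covariate marginal frequencies and ~24.5% right-censoring of a
# national demographic survey of 8810 married women (time to first birth).
# Counts are published marginal tables; they are inputs, not fitted output.

.default_region_counts <- c(
  Tigray = 852, Afar = 753, Amhara = 1001, Oromia = 1223, Somali = 902,
  Benishangul = 733, SNNPR = 1134, Gambela = 639, Harari = 510,
  AddisAbaba = 554, DireDawa = 509)

# censored / event split per region in the same survey (used by descriptive
# worked examples and tests, not by the generator itself)
.default_region_censored <- c(
  Tigray = 184, Afar = 136, Amhara = 290, Oromia = 261, Somali = 150,
  Benishangul = 183, SNNPR = 267, Gambela = 159, Harari = 128,
  AddisAbaba = 231, DireDawa = 169)

.default_marginals <- list(
  residence = c(urban = 2077, rural = 6733),
  education = c(none = 5417, primary = 2291, `secondary+` = 1102),
  wealth = c(poor = 4059, middle = 1249, rich = 3502),
  husband_education = c(none = 4150, primary = 2761, `secondary+` = 1899),
  working = c(no = 6003, yes = 2807),
  contraceptive = c(yes = 4459, no = 4351),
  age_at_marriage = c(under18 = 5513, `18-34` = 3282, over34 = 15),
  household_head = c(male = 7160, female = 1650),
  media = c(no = 6280, yes = 2530))

.default_beta <- c(
  "residence.rural" = 0.2112,
  "education.primary" = 0.1826,
  "education.secondary+" = -0.05222,
  "wealth.middle" = -0.05626,
  "wealth.rich" = -0.00962,
  "husband_education.primary" = 0.09979,
  "husband_education.secondary+" = 0.1148,
  "working.yes" = 0.005898,
  "contraceptive.no" = 0.1134,
  "age_at_marriage.18-34" = -1.385,
  "age_at_marriage.over34" = -2.864,
  "household_head.female" = -0.1682,
  "media.yes" = -0.1168)

#' Survey-structure region table
#'
#' The per-region subject, event and censored counts of the emulated survey;
#' the worked-example input for descriptive bookkeeping checks.
#'
#' @return A data.frame with columns `region`, `total`, `censored`, `events`.
#' @export
reference_region_table <- function() {
  data.frame(region = names(.default_region_counts),
             total = unname(.default_region_counts),
             censored = unname(.default_region_censored),
             events = unname(.default_region_counts -
                             .default_region_censored),
             stringsAsFactors = FALSE)
}

#' Default covariate codebook
#'
#' Nine categorical covariates with reference categories matching the
#' emulated survey's coefficient table (reference first).
#'
#' @export
default_codebook <- function()
  codebook(lapply(.default_marginals, names))

#' Synthetic-data scenario
#'
#' Describes a clustered survival-data generating process: cluster relative
#' sizes, covariate marginal frequencies (covariates drawn independently —
#' only marginals are emulated), a true [frailty_spec()], and a censoring
#' mechanism.  Defaults emulate the survey the package's fixtures are
#' patterned on: 11 regions in the published relative sizes, published
#' covariate marginals, a Weibull baseline with shape 6.1 and
#' `log(lambda) = -17.75`, coefficients at the published posterior means,
#' frailty variance `theta = 0.95`, and independent uniform administrative
#' censoring calibrated to a 24.5% censored fraction.
#'
#' @param n Number of subjects.
#' @param clusters Named vector of relative cluster sizes.
#' @param marginals Named list: per covariate, a named vector of category
#'   weights (first category = reference level).
#' @param baseline True [baseline_spec()].
#' @param beta True coefficient vector, named by design column.
#' @param theta True frailty variance (`>= 0`).
#' @param censoring List with `type` (`"uniform"`, `"exponential"` or
#'   `"none"`), optionally `max` (uniform upper bound) or `rate`
#'   (exponential), and `target` (censored fraction to calibrate to when
#'   `max`/`rate` is `NULL`).
#' @param seed Generation seed.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(n = 8810,
                          clusters = .default_region_counts,
                          marginals = .default_marginals,
                          baseline = baseline_spec("weibull",
                                                   lambda = exp(-17.75),
                                                   gamma = 6.1),
                          beta = .default_beta,
                          theta = 0.95,
                          censoring = list(type = "uniform", max = NULL,
                                           target = 0.245),
                          seed = 1L) {
  stopifnot(inherits(baseline, "baseline_spec"))
  if (n < length(clusters))
    stop("n must be at least the number of clusters", call. = FALSE)
  if (theta < 0) stop("theta must be >= 0", call. = FALSE)
  if (any(clusters <= 0)) stop("cluster sizes must be positive", call. = FALSE)
  cb <- codebook(lapply(marginals, names))
  probs <- lapply(marginals, function(w) w / sum(w))
  cols <- design_columns(cb)
  beta <- beta[cols]
  if (any(is.na(beta)))
    stop("beta must name every non-reference design column", call. = FALSE)
  names(beta) <- cols
  censoring$type <- match.arg(censoring$type,
                              c("uniform", "exponential", "none"))
  if (censoring$type != "none" && is.null(censoring$max) &&
      is.null(censoring$rate)) {
    tg <- censoring$target
    if (is.null(tg) || tg <= 0 || tg >= 1)
      stop("censoring target must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(n = as.integer(n),
                 clusters = clusters / sum(clusters),
                 cluster_names = names(clusters),
                 codebook = cb, marginals = probs,
                 baseline = baseline, beta = beta, theta = theta,
                 censoring = censoring, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Synthetic scenario: n = %d, %d clusters, theta = %g, %s censoring\n",
              x$n, length(x$clusters), x$theta, x$censoring$type))
  print(x$baseline)
  invisible(x)
}

# largest-remainder apportionment of n into the scenario's cluster sizes
apportion <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

# event times by inversion of S(t | z, x) = exp(-z H0(t) e^{x'beta})
draw_event_times <- function(baseline, scale) {
  base_invcumhaz(baseline, stats::rexp(length(scale)) / scale)
}

#' Calibrate the censoring mechanism to a target censored fraction
#'
#' Monte-Carlo root finding (common random numbers, fixed inner seed) for
#' the uniform upper bound (or exponential rate) whose expected censored
#' fraction matches the target within about half a percentage point.
#'
#' @param scenario A [scenario_spec()].
#' @param target Censored fraction in (0, 1); default the scenario's own.
#' @param nsim Monte-Carlo sample size for the root finder.
#' @param inner_seed Seed of the calibration draw (independent of the
#'   generation seed).
#' @return The calibrated censoring parameter (`max` for uniform, `rate` for
#'   exponential).
#' @export
calibrate_censoring <- function(scenario, target = NULL, nsim = 40000,
                                inner_seed = 20201L) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (is.null(target)) target <- scenario$censoring$target
  if (is.null(target) || target <= 0 || target >= 1)
    stop("target censored fraction must lie strictly in (0, 1)",
         call. = FALSE)
  if (scenario$censoring$type == "none")
    stop("scenario has no censoring mechanism to calibrate", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(inner_seed)
  sim <- simulate_latent(scenario, nsim, per_subject_z = TRUE)
  U <- stats::runif(nsim)
  f <- if (scenario$censoring$type == "uniform")
    function(b) mean(b * U < sim$T) - target
  else
    function(b) mean(-log1p(-U) / b > sim$T) - (1 - target)
  # uniform: censored fraction decreases in b; exponential: event fraction
  # increases as rate decreases
  lo <- 1e-6; hi <- 1e8
  if (f(lo) * f(hi) > 0)
    stop("no censoring parameter in the search bracket attains the target",
         call. = FALSE)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# latent covariates, frailties and uncensored event times for `m` subjects
# drawn under the scenario's cross-sectional structure (used for calibration
# and generation).  `per_subject_z` draws an independent frailty per subject
# instead of per cluster: the marginal law of each event time is identical,
# but the Monte-Carlo estimate of an expectation (e.g. the expected censored
# fraction) then integrates over the frailty distribution instead of being
# pinned to one realization of a handful of cluster frailties.
simulate_latent <- function(scenario, m, per_subject_z = FALSE) {
  sizes <- apportion(m, scenario$clusters)
  ci <- rep(seq_along(sizes), sizes)
  z <- if (scenario$theta == 0) rep(1, length(sizes))
  else if (per_subject_z) NULL
  else stats::rgamma(length(sizes), 1 / scenario$theta,
                     rate = 1 / scenario$theta)
  cov <- lapply(scenario$marginals, function(p)
    sample(names(p), m, replace = TRUE, prob = p))
  covdf <- as.data.frame(cov, check.names = FALSE,
                         stringsAsFactors = FALSE)
  X <- build_design(scenario$codebook, covdf)
  lp <- drop(X %*% scenario$beta)
  zsub <- if (is.null(z))
    stats::rgamma(m, 1 / scenario$theta, rate = 1 / scenario$theta)
  else z[ci]
  T <- draw_event_times(scenario$baseline, zsub * exp(lp))
  list(ci = ci, z = z, covdf = covdf, T = T)
}

#' Generate a clustered survival dataset from a scenario
#'
#' Draws one gamma frailty per cluster, independent covariates from the
#' stated marginals, event times by inverting the conditional survivor
#' function, and applies the (calibrated) independent censoring mechanism.
#' Fully reproducible given the scenario seed.
#'
#' @param scenario A [scenario_spec()].
#' @return A list with `dataset` (a [survival_dataset()]) and `report`
#'   (realized censored fraction, covariate frequencies, frailties, and the
#'   generating truth, including the censoring parameter actually used).
#' @export
generate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  cens <- scenario$censoring
  cens_par <- NULL
  if (cens$type == "uniform")
    cens_par <- if (!is.null(cens$max)) cens$max else
      calibrate_censoring(scenario)
  if (cens$type == "exponential")
    cens_par <- if (!is.null(cens$rate)) cens$rate else
      calibrate_censoring(scenario)
  if (!is.null(cens_par) && (!is.finite(cens_par) || cens_par <= 0))
    stop("censoring parameter must be positive and finite", call. = FALSE)

  set.seed(scenario$seed)
  sim <- simulate_latent(scenario, scenario$n)
  C <- switch(cens$type,
    none = rep(Inf, scenario$n),
    uniform = stats::runif(scenario$n, 0, cens_par),
    exponential = stats::rexp(scenario$n, rate = cens_par))
  time <- pmin(sim$T, C)
  event <- as.numeric(sim$T <= C)
  if (all(event == 0))
    stop("generated dataset has no events; censoring is infeasible",
         call. = FALSE)
  cl <- scenario$cluster_names[sim$ci]
  df <- data.frame(time = time, event = event, cluster = cl,
                   sim$covdf, check.names = FALSE, stringsAsFactors = FALSE)
  ds <- survival_dataset(df, scenario$codebook)
  report <- list(
    censored_fraction = 1 - mean(event),
    covariate_frequencies = lapply(sim$covdf, function(v)
      table(v) / length(v)),
    frailties = stats::setNames(sim$z, scenario$cluster_names),
    truth = list(baseline = scenario$baseline, beta = scenario$beta,
                 theta = scenario$theta,
                 censoring = c(cens, list(parameter = cens_par)),
                 censoring_is_assumed_mechanism = TRUE,
                 seed = scenario$seed))
  list(dataset = ds, report = report)
}
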