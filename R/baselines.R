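#' Baseline hazard specification
#'
#' Constructs a parametric baseline hazard for one of five families, all
#' parameterized on the hazard scale:
#'
#' * `exponential`: \eqn{h(t) = \lambda}
#' * `weibull`: \eqn{h(t) = \lambda \gamma t^{\gamma-1}},
#'   \eqn{S(t) = e^{-\lambda t^\gamma}} (hazard-scale `lambda`, not the
#'   `t/lambda` convention of [stats::dweibull])
#' * `gompertz`: \eqn{h(t) = \lambda e^{\theta t}}
#' * `lognormal`: \eqn{S(t) = 1 - \Phi((\log t - \mu)/\delta)}, \eqn{h = f/S}
#' * `loglogistic`: \eqn{S(t) = 1/(1 + e^\theta t^k)},
#'   \eqn{h(t) = e^\theta k t^{k-1}/(1 + e^\theta t^k)}
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"lognormal"`, `"loglogistic"`.
#' @param ... Named parameters for the family: `lambda` (exponential);
#'   `lambda`, `gamma` (weibull); `lambda`, `theta` (gompertz, `theta` may be
#'   any real including 0); `mu`, `delta` (lognormal); `theta`, `k`
#'   (loglogistic, `theta` any real, scale enters as `exp(theta)`).
#' @return An object of class `baseline_spec`.
#' @examples
#' bs <- baseline_spec("weibull", lambda = 0.5, gamma = 2)
#' base_hazard(bs, 2)
#' @export
baseline_spec <- function(family = c("exponential", "weibull", "gompertz",
                                     "lognormal", "loglogistic"), ...) {
  family <- match.arg(family)
  params <- list(...)
  wanted <- baseline_param_names(family)
  if (!setequal(names(params), wanted))
    stop(sprintf("family '%s' needs parameters: %s", family,
                 paste(wanted, collapse = ", ")), call. = FALSE)
  params <- lapply(params[wanted], as.numeric)
  pos <- switch(family,
    exponential = "lambda",
    weibull     = c("lambda", "gamma"),
    gompertz    = "lambda",
    lognormal   = "delta",
    loglogistic = "k")
  for (nm in pos)
    if (!is.finite(params[[nm]]) || params[[nm]] <= 0)
      stop(sprintf("parameter '%s' must be strictly positive", nm),
           call. = FALSE)
  for (nm in setdiff(wanted, pos))
    if (!is.finite(params[[nm]]))
      stop(sprintf("parameter '%s' must be finite", nm), call. = FALSE)
  structure(list(family = family, params = params), class = "baseline_spec")
}

baseline_param_names <- function(family) {
  switch(family,
    exponential = "lambda",
    weibull     = c("lambda", "gamma"),
    gompertz    = c("lambda", "theta"),
    lognormal   = c("mu", "delta"),
    loglogistic = c("theta", "k"),
    stop("unknown family: ", family, call. = FALSE))
}

#' @export
print.baseline_spec <- function(x, ...) {
  cat("Baseline hazard:", x$family, "\n")
  cat("  ", paste(sprintf("%s = %g", names(x$params), unlist(x$params)),
                  collapse = ", "), "\n")
  invisible(x)
}

check_time <- function(t) {
  if (any(!is.finite(t)) || any(t <= 0))
    stop("time values must be finite and strictly positive", call. = FALSE)
  t
}

# Gompertz shape |theta|*t below this uses the series expansion of
# (exp(theta*t) - 1)/theta to avoid 0/0 at theta -> 0.
.gomp_eps <- 1e-12

#' Baseline log-hazard
#'
#' @param spec A [baseline_spec()].
#' @param t Vector of positive times.
#' @return `log h0(t)`.
#' @export
base_loghaz <- function(spec, t) {
  check_time(t)
  p <- spec$params
  switch(spec$family,
    exponential = rep_len(log(p$lambda), length(t)),
    weibull     = log(p$lambda) + log(p$gamma) + (p$gamma - 1) * log(t),
    gompertz    = log(p$lambda) + p$theta * t,
    lognormal   = stats::dlnorm(t, p$mu, p$delta, log = TRUE) -
                  stats::plnorm(t, p$mu, p$delta, lower.tail = FALSE,
                                log.p = TRUE),
    loglogistic = p$theta + log(p$k) + (p$k - 1) * log(t) -
                  log1p(exp(p$theta) * t^p$k))
}

#' Baseline hazard function
#'
#' @inheritParams base_loghaz
#' @return `h0(t) >= 0`.
#' @export
base_hazard <- function(spec, t) exp(base_loghaz(spec, t))

#' Baseline cumulative hazard
#'
#' `H0(t) = integral of h0 over (0, t]`; equals `-log S0(t)`.
#'
#' @inheritParams base_loghaz
#' @export
base_cumhaz <- function(spec, t) {
  check_time(t)
  p <- spec$params
  switch(spec$family,
    exponential = p$lambda * t,
    weibull     = p$lambda * t^p$gamma,
    gompertz    = {
      th <- p$theta
      if (abs(th) < .gomp_eps) p$lambda * t
      else p$lambda * expm1(th * t) / th
    },
    lognormal   = -stats::plnorm(t, p$mu, p$delta, lower.tail = FALSE,
                                 log.p = TRUE),
    loglogistic = log1p(exp(p$theta) * t^p$k))
}

#' Baseline survivor function
#'
#' @inheritParams base_loghaz
#' @return `S0(t)` in \[0, 1\].
#' @export
base_survival <- function(spec, t) exp(-base_cumhaz(spec, t))

#' Baseline density
#'
#' `f(t) = h0(t) * S0(t)`.
#'
#' @inheritParams base_loghaz
#' @export
base_density <- function(spec, t) exp(base_loghaz(spec, t) - base_cumhaz(spec, t))

#' Invert the baseline cumulative hazard
#'
#' Solves `H0(t) = H` for `t`; the workhorse for inversion sampling of event
#' times, including frailty/covariate-modified hazards (which rescale `H`).
#'
#' @param spec A [baseline_spec()].
#' @param H Vector of nonnegative cumulative-hazard values.
#' @export
base_invcumhaz <- function(spec, H) {
  if (any(!is.finite(H)) || any(H < 0))
    stop("cumulative hazard values must be finite and nonnegative",
         call. = FALSE)
  p <- spec$params
  switch(spec$family,
    exponential = H / p$lambda,
    weibull     = (H / p$lambda)^(1 / p$gamma),
    gompertz    = {
      th <- p$theta
      if (abs(th) < .gomp_eps) H / p$lambda
      else {
        arg <- th * H / p$lambda
        if (th < 0 && any(arg <= -1))
          stop("cumulative hazard not attainable: Gompertz with negative ",
               "shape has bounded total hazard", call. = FALSE)
        log1p(arg) / th
      }
    },
    lognormal   = stats::qlnorm(-H, p$mu, p$delta, lower.tail = FALSE,
                                log.p = TRUE),
    loglogistic = (expm1(H) * exp(-p$theta))^(1 / p$k))
}

#' Baseline quantile function
#'
#' Time `t` with `S0(t) = 1 - prob`.
#'
#' @param spec A [baseline_spec()].
#' @param prob Vector of probabilities in (0, 1).
#' @export
base_quantile <- function(spec, prob) {
  if (any(prob <= 0) || any(prob >= 1))
    stop("prob must lie strictly in (0, 1)", call. = FALSE)
  base_invcumhaz(spec, -log1p(-prob))
}

#' Sample from a baseline distribution
#'
#' Inversion sampling: `t = H0^{-1}(-log U)` with `U ~ Uniform(0, 1)`.
#' Reproducible under [set.seed()].
#'
#' @param spec A [baseline_spec()].
#' @param n Number of draws.
#' @export
base_sample <- function(spec, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive count", call. = FALSE)
  base_invcumhaz(spec, stats::rexp(n))
}
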