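#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator with simultaneous decrement at tied event times
#' and Greenwood pointwise variance, computed via [survival::survfit()].
#'
#' @param ds A [survival_dataset()].
#' @param conf Confidence level for the pointwise band (log(-log)
#'   transformed), default 0.95.
#' @return An object of class `km_estimate` with the event-time grid,
#'   at-risk/event counts, `surv`, Greenwood `std_err` (of `Ŝ`), and the
#'   underlying `survfit` object.
#' @export
kaplan_meier <- function(ds, conf = 0.95) {
  stopifnot(inherits(ds, "survival_dataset"))
  fit <- survival::survfit(
    survival::Surv(ds$data$time, ds$data$event) ~ 1,
    conf.type = "log-log", conf.int = conf)
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv, std_err = fit$std.err * fit$surv,
                 lower = fit$lower, upper = fit$upper,
                 conf = conf, survfit = fit),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate on %d distinct times; final S = %.4f\n",
              length(x$time), min(x$surv)))
  invisible(x)
}

#' Median survival time with confidence interval
#'
#' The median is the smallest observed time with `Ŝ(t) <= 0.5`; its interval
#' comes from inverting the log(-log)-transformed pointwise confidence band.
#' If `Ŝ` never reaches 0.5 the median is undefined and all three values are
#' returned as `NA` (no error is raised).
#'
#' @param km A [kaplan_meier()] result.
#' @param conf Confidence level; must match the one the band was built with.
#' @return Named numeric vector `c(median, lower, upper)`.
#' @export
median_survival <- function(km, conf = 0.95) {
  stopifnot(inherits(km, "km_estimate"))
  if (abs(conf - km$conf) > 1e-12)
    stop("conf does not match the band stored in the KM estimate",
         call. = FALSE)
  tab <- summary(km$survfit)$table
  # median by definition (smallest observed time with S <= 0.5); the
  # survfit table instead averages across an exactly-0.5 plateau
  med <- if (min(km$surv) <= 0.5) min(km$time[km$surv <= 0.5]) else NA_real_
  out <- c(med,
           unname(tab[grep("LCL$", names(tab))]),
           unname(tab[grep("UCL$", names(tab))]))
  names(out) <- c("median", "lower", "upper")
  if (is.na(med)) out[] <- NA_real_
  out
}

#' K-sample log-rank test
#'
#' Standard (unweighted) log-rank chi-square across the levels of one
#' categorical covariate, ties handled by the hypergeometric variance;
#' computed via [survival::survdiff()].
#'
#' @param ds A [survival_dataset()].
#' @param covariate Name of a covariate column (or `"cluster"`).
#' @return An object of class `logrank_result`: `statistic`, `df` (K - 1),
#'   `p_value`, and the per-group observed/expected table.
#' @export
log_rank <- function(ds, covariate) {
  stopifnot(inherits(ds, "survival_dataset"))
  if (!covariate %in% names(ds$data))
    stop("no such covariate: ", covariate, call. = FALSE)
  g <- factor(ds$data[[covariate]])
  if (nlevels(g) < 2)
    stop("log-rank needs at least two nonempty groups", call. = FALSE)
  sd <- survival::survdiff(
    survival::Surv(ds$data$time, ds$data$event) ~ g)
  df <- nlevels(g) - 1L
  structure(list(covariate = covariate, statistic = unname(sd$chisq),
                 df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 observed = sd$obs, expected = sd$exp,
                 groups = levels(g)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test on '%s': chi-square = %.4g, df = %d, p = %.3g\n",
              x$covariate, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Log-rank report across covariates
#'
#' One row per covariate: K-sample log-rank statistic, degrees of freedom and
#' p-value, in the style of a survey comparison table.
#'
#' @param ds A [survival_dataset()].
#' @param covariates Covariate names; default all codebook covariates plus
#'   the cluster label.
#' @export
log_rank_table <- function(ds, covariates = NULL) {
  stopifnot(inherits(ds, "survival_dataset"))
  if (is.null(covariates))
    covariates <- c("cluster", names(ds$codebook$levels))
  do.call(rbind, lapply(covariates, function(v) {
    lr <- log_rank(ds, v)
    data.frame(variable = v, statistic = lr$statistic, df = lr$df,
               p_value = lr$p_value, stringsAsFactors = FALSE)
  }))
}
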