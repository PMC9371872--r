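#' Posterior summary table
#'
#' Pooled-across-chains posterior mean, standard deviation, Monte Carlo
#' error, median and equal-tailed 95% interval for each monitored parameter.
#' The MC error uses the batch-means estimator (50 batches per chain,
#' combined across chains).  A parameter whose 95% interval excludes 0 is
#' flagged as significant, the convention used for coefficient tables.
#'
#' @param chains A [run_mcmc()] result (`gsf_chains`).
#' @param params Parameter names to summarize; default the monitored set
#'   (baseline parameters, coefficients, `theta` — not the frailties).
#' @param prob Interval probability (default 0.95).
#' @return A data.frame with columns `parameter`, `mean`, `sd`, `mc_error`,
#'   `median`, `lower`, `upper`, `start`, `sample`, `significant`,
#'   `mc_error_ok` (MC error below 5% of the SD).
#' @export
summarize_posterior <- function(chains, params = NULL, prob = 0.95) {
  stopifnot(inherits(chains, "gsf_chains"))
  if (is.null(params)) params <- chains$monitor
  if (chains$iters < 1) stop("no post-burn-in samples", call. = FALSE)
  a <- (1 - prob) / 2
  rows <- lapply(params, function(pm) {
    per_chain <- lapply(chains$samples, function(m) m[, pm])
    x <- unlist(per_chain, use.names = FALSE)
    mce <- batch_means_error(per_chain)
    s <- stats::sd(x)
    q <- stats::quantile(x, c(a, 0.5, 1 - a), names = FALSE, type = 7)
    data.frame(parameter = pm, mean = mean(x), sd = s, mc_error = mce,
               median = q[2], lower = q[1], upper = q[3],
               start = chains$burnin + 1L,
               sample = length(x),
               significant = q[1] > 0 | q[3] < 0,
               mc_error_ok = is.na(s) || s == 0 || mce < 0.05 * s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Batch-means Monte Carlo standard error of the pooled posterior mean.
# Each chain is cut into `nbatch` equal batches (remainder dropped); the
# chain-level squared errors combine as independent estimates of the chain
# means, whose average is the pooled estimate.
batch_means_error <- function(per_chain, nbatch = 50) {
  ses <- vapply(per_chain, function(x) {
    m <- length(x)
    B <- min(nbatch, m)
    size <- floor(m / B)
    if (size < 1) return(NA_real_)
    bm <- colMeans(matrix(x[seq_len(B * size)], nrow = size))
    if (B < 2) return(NA_real_)
    stats::sd(bm) / sqrt(B)
  }, numeric(1))
  sqrt(sum(ses^2)) / length(ses)
}

#' Deviance information criterion
#'
#' `Dbar` is the posterior mean of the deviance, `Dhat` the deviance at the
#' posterior means of the parameters, `pD = Dbar - Dhat`, `DIC = Dbar + pD`.
#' By default the deviance uses the marginal likelihood (frailties
#' integrated out), so frailty and no-frailty models are directly
#' comparable; `focus = "conditional"` instead plugs the sampled frailties
#' into the complete-data likelihood.
#'
#' @param chains A [run_mcmc()] result.
#' @param ds The [survival_dataset()] the chains were run on.
#' @param focus `"marginal"` (default) or `"conditional"`.
#' @param max_draws Cap on the number of stored draws used for `Dbar`
#'   (evenly thinned; default 1000).  `Dhat` always uses the full posterior
#'   means.
#' @return An object of class `dic_report` with `Dbar`, `Dhat`, `pD`, `DIC`.
#' @export
compute_dic <- function(chains, ds, focus = c("marginal", "conditional"),
                        max_draws = 1000) {
  stopifnot(inherits(chains, "gsf_chains"), inherits(ds, "survival_dataset"))
  focus <- match.arg(focus)
  info <- baseline_tinfo(chains$family)
  nb <- length(info$names)
  bnames <- colnames(ds$X)
  labs <- chains$cluster_labels

  all_draws <- do.call(rbind, chains$samples)
  ndraw <- nrow(all_draws)
  idx <- if (ndraw > max_draws)
    unique(round(seq(1, ndraw, length.out = max_draws))) else seq_len(ndraw)

  spec_at <- function(row) {
    bl <- do.call(baseline_spec, c(list(family = chains$family),
                                   as.list(row[info$names])))
    frailty_spec(bl, stats::setNames(row[bnames], bnames),
                 if (chains$frailty) row["theta"] else 0)
  }
  dev_at <- function(row) {
    sp <- spec_at(row)
    if (focus == "marginal") -2 * marginal_loglik(sp, ds)
    else -2 * complete_data_loglik(
      sp, ds, stats::setNames(row[paste0("z.", labs)], labs))
  }

  devs <- apply(all_draws[idx, , drop = FALSE], 1, dev_at)
  Dbar <- mean(devs)
  Dhat <- dev_at(colMeans(all_draws))
  pD <- Dbar - Dhat
  structure(list(Dbar = Dbar, Dhat = Dhat, pD = pD, DIC = Dbar + pD,
                 focus = focus, n_draws = length(idx),
                 family = chains$family, frailty = chains$frailty),
            class = "dic_report")
}

#' @export
print.dic_report <- function(x, ...) {
  cat(sprintf("DIC (%s deviance): Dbar %.3f  Dhat %.3f  pD %.3f  DIC %.3f\n",
              x$focus, x$Dbar, x$Dhat, x$pD, x$DIC))
  invisible(x)
}

#' Brooks-Gelman-Rubin diagnostic (interval ratio)
#'
#' The ratio of the width of the pooled central 80% interval to the average
#' within-chain central 80% interval width, computed over an expanding
#' sequence of iteration windows (the second half of each window is used).
#' Values near 1 indicate convergence; duplicated chains give exactly 1.
#'
#' @param chains A [run_mcmc()] result, or a list of numeric vectors (one
#'   per chain) for a single parameter.
#' @param parameter Parameter name (ignored when `chains` is a plain list).
#' @param nwindows Number of expanding windows for the plotted series.
#' @param interval Central interval mass (default 0.80, the WinBUGS choice).
#' @return An object of class `bgr_diagnostic`: final `psrf` and a data.frame
#'   `series` with columns `iteration`, `pooled`, `within`, `ratio`.
#' @export
bgr_diagnostic <- function(chains, parameter = NULL, nwindows = 20,
                           interval = 0.8) {
  if (inherits(chains, "gsf_chains")) {
    if (is.null(parameter))
      stop("parameter must be named for a gsf_chains object", call. = FALSE)
    draws <- lapply(chains$samples, function(m) m[, parameter])
  } else draws <- lapply(chains, as.numeric)
  if (length(draws) < 2)
    stop("the diagnostic needs at least two chains", call. = FALSE)
  m <- min(lengths(draws))
  if (m < 4) stop("chains are too short", call. = FALSE)
  a <- (1 - interval) / 2
  width <- function(x)
    diff(stats::quantile(x, c(a, 1 - a), names = FALSE, type = 1))
  cuts <- unique(pmax(4, round(seq(m / nwindows, m, length.out = nwindows))))
  series <- do.call(rbind, lapply(cuts, function(cut) {
    sel <- seq(floor(cut / 2) + 1, cut)   # second half of the window
    w <- mean(vapply(draws, function(x) width(x[sel]), numeric(1)))
    pool <- width(unlist(lapply(draws, `[`, sel), use.names = FALSE))
    data.frame(iteration = cut, pooled = pool, within = w,
               ratio = if (w > 0) pool / w else if (pool == 0) 1 else Inf)
  }))
  structure(list(psrf = series$ratio[nrow(series)], series = series,
                 parameter = parameter),
            class = "bgr_diagnostic")
}

#' @export
print.bgr_diagnostic <- function(x, ...) {
  cat(sprintf("BGR interval-ratio diagnostic%s: %.4f\n",
              if (is.null(x$parameter)) "" else paste0(" [", x$parameter, "]"),
              x$psrf))
  invisible(x)
}

#' Trace, density and BGR plots for monitored parameters
#'
#' Writes one PNG per monitored parameter and plot type (`trace_<p>.png`,
#' `density_<p>.png`, `bgr_<p>.png`) into `dir`.  Deterministic filenames;
#' existing files are overwritten.
#'
#' @param chains A [run_mcmc()] result.
#' @param dir Output directory (created if missing).
#' @param params Parameters to plot; default the monitored set.
#' @param width,height Device size in pixels.
#' @return Invisible character vector of the files written.
#' @export
convergence_plots <- function(chains, dir, params = NULL,
                              width = 640, height = 400) {
  stopifnot(inherits(chains, "gsf_chains"))
  if (is.null(params)) params <- chains$monitor
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  safe <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
  for (pm in params) {
    draws <- lapply(chains$samples, function(m) m[, pm])
    f <- file.path(dir, paste0("trace_", safe(pm), ".png"))
    grDevices::png(f, width, height)
    graphics::matplot(do.call(cbind, draws), type = "l", lty = 1,
                      xlab = "kept iteration", ylab = pm,
                      main = paste("History:", pm))
    grDevices::dev.off(); files <- c(files, f)

    f <- file.path(dir, paste0("density_", safe(pm), ".png"))
    grDevices::png(f, width, height)
    x <- unlist(draws, use.names = FALSE)
    if (stats::sd(x) > 0) graphics::plot(stats::density(x),
                                         main = paste("Density:", pm))
    else graphics::plot(x[1], 1, pch = 16,
                        main = paste("Density (degenerate):", pm),
                        xlab = pm, ylab = "")
    grDevices::dev.off(); files <- c(files, f)

    if (chains$chains >= 2) {
      b <- bgr_diagnostic(chains, pm)
      f <- file.path(dir, paste0("bgr_", safe(pm), ".png"))
      grDevices::png(f, width, height)
      graphics::plot(b$series$iteration, b$series$ratio, type = "l",
                     col = "red", ylim = range(0, 1.2, b$series$ratio),
                     xlab = "iteration window", ylab = "interval ratio",
                     main = paste("BGR:", pm))
      norm <- max(b$series$pooled)
      if (norm > 0) {
        graphics::lines(b$series$iteration, b$series$pooled / norm,
                        col = "darkgreen")
        graphics::lines(b$series$iteration, b$series$within / norm,
                        col = "blue")
      }
      graphics::abline(h = 1, lty = 2)
      grDevices::dev.off(); files <- c(files, f)
    }
  }
  invisible(files)
}

#' Hazard ratios from a posterior (or coefficient) summary
#'
#' `HR = exp(mean)` with credible interval endpoints `exp(lower)` and
#' `exp(upper)`.  Full precision is kept; use `signif()` for display.
#'
#' @param summary A data.frame with columns `parameter`, `mean`, `lower`,
#'   `upper` (as produced by [summarize_posterior()]), or any subset of rows
#'   of one.
#' @return A data.frame with columns `parameter`, `hr`, `hr_lower`,
#'   `hr_upper`.
#' @export
hazard_ratio_table <- function(summary) {
  need <- c("parameter", "mean", "lower", "upper")
  if (!all(need %in% names(summary)))
    stop("summary must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  data.frame(parameter = summary$parameter,
             hr = exp(summary$mean),
             hr_lower = exp(summary$lower),
             hr_upper = exp(summary$upper),
             stringsAsFactors = FALSE)
}
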