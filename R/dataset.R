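#' Clustered survival dataset
#'
#' Validates and indexes one row per subject: a positive observed time
#' (years), an event indicator (1 = event observed, 0 = right-censored), a
#' cluster label (e.g. region), and the categorical covariates declared by a
#' [codebook()].  Rows with missing covariate values are rejected with a
#' row-indexed error; analysis is complete-case only.
#'
#' @param data A data.frame with columns `time`, `event`, `cluster` and one
#'   column per codebook covariate.
#' @param cb A [codebook()]; may be `NULL` for covariate-free data.
#' @return An object of class `survival_dataset` with elements `data`,
#'   `codebook`, `X` (dummy design matrix), `cluster` (factor),
#'   `cluster_index`, `n`, `r` (number of clusters) and `n_i` (cluster sizes).
#' @export
survival_dataset <- function(data, cb = NULL) {
  req <- c("time", "event", "cluster")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(cb)) {
    stopifnot(inherits(cb, "codebook"))
    miss <- setdiff(names(cb$levels), names(data))
    if (length(miss))
      stop("missing covariate column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  n <- nrow(data)
  if (n < 1L) stop("dataset is empty", call. = FALSE)

  time <- suppressWarnings(as.numeric(data$time))
  event <- suppressWarnings(as.numeric(data$event))
  bad <- which(!is.finite(time) | time <= 0)
  if (length(bad))
    stop(sprintf("row %d: time must be a positive number (got '%s')",
                 bad[1], as.character(data$time[bad[1]])), call. = FALSE)
  bad <- which(!(event %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("row %d: event must be 0 or 1 (got '%s')",
                 bad[1], as.character(data$event[bad[1]])), call. = FALSE)
  cl <- as.character(data$cluster)
  bad <- which(is.na(cl) | cl == "")
  if (length(bad))
    stop(sprintf("row %d: cluster label must be non-empty", bad[1]),
         call. = FALSE)

  covnames <- if (is.null(cb)) character(0) else names(cb$levels)
  for (nm in covnames) {
    bad <- which(is.na(data[[nm]]))
    if (length(bad))
      stop(sprintf("row %d: missing value for covariate '%s'", bad[1], nm),
           call. = FALSE)
  }
  X <- if (is.null(cb)) matrix(0, n, 0) else build_design(cb, data)

  cluster <- factor(cl, levels = unique(cl))
  n_i <- as.vector(table(cluster))
  names(n_i) <- levels(cluster)
  out <- data.frame(time = time, event = event, cluster = cl,
                    data[covnames], stringsAsFactors = FALSE,
                    check.names = FALSE)
  structure(list(data = out, codebook = cb, X = X, cluster = cluster,
                 cluster_index = as.integer(cluster), n = n,
                 r = nlevels(cluster), n_i = n_i),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("Clustered survival dataset: n = %d subjects, %d events (%.1f%%), r = %d clusters\n",
              x$n, sum(x$data$event), 100 * mean(x$data$event), x$r))
  if (!is.null(x$codebook))
    cat("  covariates:", paste(names(x$codebook$levels), collapse = ", "), "\n")
  invisible(x)
}

#' Read a clustered survival dataset from CSV
#'
#' Comma-separated, UTF-8, header row required, `.` decimal.  Unparseable
#' time/event fields and unknown covariate categories are rejected with
#' row-indexed errors, never silently dropped.
#'
#' @param path Path to the CSV file.
#' @param cb A [codebook()] (or `NULL` for covariate-free data).
#' @export
read_dataset <- function(path, cb = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  survival_dataset(raw, cb)
}

#' Write a clustered survival dataset to CSV
#'
#' Inverse of [read_dataset()]: the written file reads back to an identical
#' set of records.
#'
#' @param ds A [survival_dataset()].
#' @param path Output path.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "survival_dataset"))
  utils::write.csv(ds$data, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Descriptive event/censoring table
#'
#' Counts and percentages of events and censored observations per cluster and
#' per covariate level, in the style of a survey descriptive table.
#' Percentages are `100 * count / n` rounded to one decimal for display; the
#' returned counts are exact.
#'
#' @param ds A [survival_dataset()].
#' @return A data.frame with columns `variable`, `category`, `total`,
#'   `events`, `censored`, `pct_of_n`, `event_pct_within`.
#' @export
summarize_dataset <- function(ds) {
  stopifnot(inherits(ds, "survival_dataset"))
  if (ds$n < 1L) stop("dataset is empty", call. = FALSE)
  ev <- ds$data$event
  one <- function(variable, value) {
    out <- lapply(unique(value), function(v) {
      sel <- value == v
      data.frame(variable = variable, category = v,
                 total = sum(sel), events = sum(ev[sel]),
                 censored = sum(sel) - sum(ev[sel]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  pieces <- list(
    data.frame(variable = "overall", category = "all", total = ds$n,
               events = sum(ev), censored = ds$n - sum(ev),
               stringsAsFactors = FALSE),
    one("cluster", ds$data$cluster))
  for (nm in names(ds$codebook$levels))
    pieces <- c(pieces, list(one(nm, as.character(ds$data[[nm]]))))
  tab <- do.call(rbind, pieces)
  tab$pct_of_n <- round(100 * tab$total / ds$n, 1)
  tab$event_pct_within <- round(100 * tab$events / tab$total, 1)
  rownames(tab) <- NULL
  tab
}
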