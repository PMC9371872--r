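#' Covariate codebook
#'
#' Declares, for each categorical covariate, the ordered category list with
#' the first entry as the reference level.  The codebook fixes the dummy
#' (one-hot-minus-reference) encoding used to build design matrices, so that
#' fitted coefficients always refer to explicit, stable contrasts.
#'
#' @param levels A named list; each element is a character vector of category
#'   labels in order, the first being the reference.
#' @return An object of class `codebook`.
#' @examples
#' cb <- codebook(list(residence = c("urban", "rural")))
#' @export
codebook <- function(levels) {
  if (!is.list(levels) || is.null(names(levels)) || any(names(levels) == ""))
    stop("levels must be a named list of category vectors", call. = FALSE)
  levels <- lapply(levels, as.character)
  for (nm in names(levels)) {
    lv <- levels[[nm]]
    if (length(lv) < 2L)
      stop(sprintf("covariate '%s' needs at least two categories", nm),
           call. = FALSE)
    if (anyDuplicated(lv))
      stop(sprintf("covariate '%s' has duplicated categories", nm),
           call. = FALSE)
  }
  structure(list(levels = levels), class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat("Covariate codebook (", length(x$levels), " covariates)\n", sep = "")
  for (nm in names(x$levels)) {
    lv <- x$levels[[nm]]
    cat(sprintf("  %s: %s (ref) | %s\n", nm, lv[1],
                paste(lv[-1], collapse = ", ")))
  }
  invisible(x)
}

#' Read a codebook from a YAML or JSON file
#'
#' The file maps each covariate name to its ordered category list, first
#' entry = reference.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  codebook(raw)
}

#' Write a codebook to YAML
#'
#' @param cb A [codebook()].
#' @param path Output path.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  yaml::write_yaml(cb$levels, path)
  invisible(path)
}

#' Design-matrix columns implied by a codebook
#'
#' One column per non-reference category, named `covariate.category`.
#'
#' @param cb A [codebook()].
#' @export
design_columns <- function(cb) {
  stopifnot(inherits(cb, "codebook"))
  unlist(lapply(names(cb$levels), function(nm)
    paste(nm, cb$levels[[nm]][-1], sep = ".")), use.names = FALSE)
}

# Dummy design matrix for a data.frame of category labels, in codebook order.
# Unknown categories are reported with the offending rows.
build_design <- function(cb, covdata) {
  n <- nrow(covdata)
  cols <- design_columns(cb)
  X <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  for (nm in names(cb$levels)) {
    lv <- cb$levels[[nm]]
    val <- as.character(covdata[[nm]])
    bad <- which(!(val %in% lv))
    if (length(bad))
      stop(sprintf(
        "covariate '%s': category '%s' at row %d is not in the codebook",
        nm, val[bad[1]], bad[1]), call. = FALSE)
    for (cat in lv[-1])
      X[, paste(nm, cat, sep = ".")] <- as.numeric(val == cat)
  }
  X
}
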