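#' Read and write the package's delimited and JSON artifacts
#'
#' All delimited outputs carry a one-line provenance comment header
#' (`# lifeyears <version> seed=<seed> ...`); readers skip `#` comments.
#' Fits serialise to a small JSON document with family, parameter vector and
#' likelihood metadata, so a model can be re-used (e.g. for external
#' validation) without the cohort it was fitted to.
#'
#' @param path File path.
#' @param x Object to write.
#' @param seed Optional seed recorded in the header.
#' @return `read_cohort()`/`read_quantile_table()` return tibbles;
#'   `read_fit()` returns a `parametric_fit`; writers return the path
#'   invisibly.
#' @name io
NULL

# deliberately free of wall-clock fields: identical inputs and seed must give
# byte-identical artifacts
meta_header <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("lifeyears"))
  paste0("# lifeyears ", v,
         if (!is.null(seed)) paste0(" seed=", seed) else "")
}

#' @rdname io
#' @export
write_table_with_meta <- function(x, path, seed = NULL) {
  writeLines(meta_header(seed), path)
  suppressWarnings(
    readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  )
  invisible(path)
}

#' @rdname io
#' @export
read_cohort <- function(path) {
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!"group" %in% names(d) && "points" %in% names(d)) {
    d$group <- pmin(as.integer(d$points), 14L)
  }
  as_survival_records(d)
}

#' @rdname io
#' @export
read_quantile_table <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' @rdname io
#' @export
write_fit <- function(x, path) {
  stopifnot(inherits(x, "parametric_fit"))
  doc <- x
  class(doc) <- NULL
  doc$rates <- as.list(doc$rates)
  doc$beta <- as.list(doc$beta)
  doc$package_version <- as.character(utils::packageVersion("lifeyears"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname io
#' @export
read_fit <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  rates <- unlist(doc$rates)
  beta <- if (length(doc$beta)) unlist(doc$beta) else numeric(0)
  structure(list(
    family = doc$family,
    shape = if (is.null(doc$shape)) NA_real_ else doc$shape,
    shape_se = if (is.null(doc$shape_se)) NA_real_ else doc$shape_se,
    rates = rates,
    beta0 = doc$beta0,
    beta = beta,
    loglik = if (is.null(doc$loglik)) NA_real_ else doc$loglik,
    n_params = doc$n_params,
    aic = if (is.null(doc$aic)) NA_real_ else doc$aic,
    bic = if (is.null(doc$bic)) NA_real_ else doc$bic,
    n = if (is.null(doc$n)) NA_integer_ else doc$n,
    n_events = if (is.null(doc$n_events)) NA_integer_ else doc$n_events,
    converged = isTRUE(doc$converged),
    horizon = if (is.null(doc$horizon)) 10 else doc$horizon,
    source = doc$source
  ), class = "parametric_fit")
}
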