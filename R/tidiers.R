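#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted parametric survival model
#'
#' One row per parameter: the shared shape, the log baseline rate of the
#' first group (`beta0`), and the log hazard ratio of each remaining group
#' versus the first. Rates themselves are exposed via the `rate` column.
#'
#' @param x A `parametric_fit`.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `rate` (per-group rate where the term
#'   is group-specific, `NA` for the shape), `std.error` (shape only).
#' @export
tidy.parametric_fit <- function(x, ...) {
  groups <- names(x$rates)
  rows <- tibble::tibble(
    term = c(if (!is.na(x$shape)) "shape",
             "beta0",
             if (length(groups) > 1) paste0("group", groups[-1])),
    estimate = c(if (!is.na(x$shape)) x$shape, x$beta0, x$beta),
    rate = c(if (!is.na(x$shape)) NA_real_, unname(x$rates)),
    std.error = NA_real_
  )
  if (!is.na(x$shape)) rows$std.error[1] <- x$shape_se
  rows
}

#' Glance at a fitted parametric survival model
#'
#' @param x A `parametric_fit`.
#' @param ... Unused.
#' @return One-row tibble: `family`, `shape`, `logLik`, `AIC`, `BIC`, `df`,
#'   `nobs`, `n_events`, `converged`, `source`.
#' @export
glance.parametric_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    shape = x$shape,
    logLik = x$loglik,
    AIC = x$aic,
    BIC = x$bic,
    df = as.integer(x$n_params),
    nobs = x$n,
    n_events = x$n_events,
    converged = x$converged,
    source = x$source
  )
}
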