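#' Right-censored log-likelihood for grouped parametric survival models
#'
#' Evaluates the censored log-likelihood
#' \deqn{\ell = \sum_{deaths} \log h_g(t_i) - \sum_{all} H_g(t_i)}
#' for a proportional-hazards model in which every member of risk group
#' \eqn{g} shares a rate \eqn{\lambda_g} and all groups share one shape.
#' Families: `"gompertz"` (\eqn{h = \lambda e^{\gamma t}}), `"weibull"` in its
#' proportional-hazards form (\eqn{h = \lambda \alpha t^{\alpha-1}}), and
#' `"exponential"` (\eqn{h = \lambda}; no shape).
#'
#' @param data Data frame of survival records with columns `group`,
#'   `time_years` (non-negative, years from baseline) and `event`
#'   (logical/0-1; `TRUE` = death observed, `FALSE` = right-censored).
#' @param rates Named numeric vector of per-group rates; names are group
#'   labels covering every group present in `data`.
#' @param shape Shared shape parameter (ignored for `"exponential"`).
#' @param family `"gompertz"`, `"weibull"` or `"exponential"`.
#' @return The log-likelihood (scalar).
#' @examples
#' d <- data.frame(group = "0", time_years = 2, event = TRUE)
#' survival_loglik(d, rates = c("0" = 1), shape = 0)  # log(1) - 2
#' @export
survival_loglik <- function(data, rates, shape = 0,
                            family = c("gompertz", "weibull", "exponential")) {
  family <- match.arg(family)
  rec <- as_survival_records(data)
  if (!any(rec$event)) {
    stop("degenerate likelihood: the cohort contains no observed deaths.",
         call. = FALSE)
  }
  g <- as.character(rec$group)
  if (!all(g %in% names(rates))) {
    stop("`rates` must name every group present in the data.", call. = FALSE)
  }
  lam <- rates[g]
  t <- rec$time_years
  ev <- rec$event
  switch(family,
    gompertz = sum(log(lam[ev]) + shape * t[ev]) -
      sum(lam * t * expm1_over_x(shape * t)),
    weibull = sum(log(lam[ev]) + log(shape) + (shape - 1) * log(t[ev])) -
      sum(lam * t^shape),
    exponential = sum(log(lam[ev])) - sum(lam * t)
  )
}

# validate and normalise a cohort data frame; events at exactly t = 0 are
# nudged by half a day so the density term stays finite
as_survival_records <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("group", "time_years", "event")
  absent <- setdiff(need, names(data))
  if (length(absent) > 0) {
    stop("cohort data must have column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0) stop("empty cohort.", call. = FALSE)
  out <- tibble::tibble(
    group = as_group_factor(data$group),
    time_years = as.numeric(data$time_years),
    event = as.logical(data$event)
  )
  if (any(is.na(out$time_years)) || any(out$time_years < 0)) {
    stop("`time_years` must be non-negative follow-up in years.",
         call. = FALSE)
  }
  if (any(is.na(out$event))) stop("`event` must be 0/1.", call. = FALSE)
  zero_events <- out$time_years <= 0 & out$event
  if (any(zero_events)) {
    message(sum(zero_events),
            " death(s) recorded at time 0 offset to 0.0014 years (half a day).")
    out$time_years[zero_events] <- 0.0014
  }
  out
}

# per-group sufficient statistics for the profile likelihood:
# given the shape, the MLE of each group rate is deaths / "generalised
# exposure" A_g, where A_g is the per-group sum of t*phi(shape*t) (gompertz),
# t^shape (weibull) or t (exponential).
profile_stats <- function(rec) {
  grp <- droplevels(rec$group)
  list(
    grp = grp,
    levels = levels(grp),
    d = tapply(rec$event, grp, sum),
    t = rec$time_years,
    ev = rec$event,
    sum_t_events = sum(rec$time_years[rec$event]),
    sum_logt_events = sum(log(rec$time_years[rec$event]))
  )
}

profile_loglik <- function(shape, ps, family) {
  a_i <- switch(family,
    gompertz = ps$t * expm1_over_x(shape * ps$t),
    weibull = ps$t^shape,
    exponential = ps$t
  )
  A <- tapply(a_i, ps$grp, sum)
  d <- ps$d
  pos <- d > 0
  core <- sum(d[pos] * log(d[pos] / A[pos])) - sum(d)
  core + switch(family,
    gompertz = shape * ps$sum_t_events,
    weibull = sum(d) * log(shape) + (shape - 1) * ps$sum_logt_events,
    exponential = 0
  )
}

profile_rates <- function(shape, ps, family) {
  a_i <- switch(family,
    gompertz = ps$t * expm1_over_x(shape * ps$t),
    weibull = ps$t^shape,
    exponential = ps$t
  )
  A <- tapply(a_i, ps$grp, sum)
  rates <- as.numeric(ps$d / A)
  names(rates) <- ps$levels
  rates
}

#' Fit a shared-shape parametric survival model to a grouped cohort
#'
#' Maximum-likelihood fit of a proportional-hazards survival model with the
#' risk-point group as a categorical covariate: every group has its own rate
#' \eqn{\lambda_g = \exp(\beta_0 + \beta_g)} and all groups share one shape.
#' For the default Gompertz family this is the model behind the
#' life-expectancy calculator; Weibull (proportional-hazards form) and
#' exponential fits are provided for information-criterion comparison.
#'
#' Because the covariate is categorical, the rate MLEs are available in
#' closed form given the shape (deaths over generalised exposure), so the fit
#' reduces to a one-dimensional profile-likelihood maximisation over the
#' shape on a fixed bracket — deterministic, with no starting-value
#' sensitivity. The shape is unconstrained: a negative Gompertz shape (hazard
#' decaying in time) is legal but triggers a warning because deep survival
#' quantiles may then be unattainable.
#'
#' @inheritParams survival_loglik
#' @param family Parametric family to fit.
#' @param shape_bracket Search interval for the shared shape. Defaults cover
#'   hazard-doubling times from about 6 months upwards (Gompertz) or Weibull
#'   shapes 0.05–25.
#' @return An object of class `parametric_fit`: a list with `family`,
#'   `shape`, `shape_se`, `rates` (named per-group vector), `beta0`/`beta`
#'   (log baseline rate and log hazard ratios vs the first group), `loglik`,
#'   `n_params`, `aic`, `bic`, `n`, `n_events`, `converged`, `horizon`
#'   (maximum observed follow-up, used to flag extrapolation downstream).
#'   Methods: [tidy()], [glance()], `print()`, [predict_life_expectancy()].
#' @examples
#' spec <- hrs_cohort_spec("development")
#' cohort <- sample_cohort(spec, n = 2000, seed = 1)
#' fit <- fit_parametric(cohort)
#' glance(fit)
#' @export
fit_parametric <- function(data,
                           family = c("gompertz", "weibull", "exponential"),
                           shape_bracket = NULL) {
  family <- match.arg(family)
  rec <- as_survival_records(data)
  if (!any(rec$event)) {
    stop("degenerate likelihood: the cohort contains no observed deaths.",
         call. = FALSE)
  }
  ps <- profile_stats(rec)
  if (any(ps$d == 0)) {
    warning("group(s) with exposure but no observed deaths: ",
            paste(ps$levels[ps$d == 0], collapse = ", "),
            "; their rate is estimated at 0 and quantiles are undefined.",
            call. = FALSE)
  }
  if (family == "weibull" && any(rec$time_years == 0)) {
    # zero-time censored records contribute nothing to a Weibull fit anyway
    rec$time_years[rec$time_years == 0] <- 1e-8
    ps <- profile_stats(rec)
  }

  converged <- TRUE
  if (family == "exponential") {
    shape <- NA_real_
    shape_se <- NA_real_
  } else {
    if (is.null(shape_bracket)) {
      shape_bracket <- if (family == "gompertz") c(-1, 1.5) else c(0.05, 25)
    }
    opt <- stats::optimize(profile_loglik, shape_bracket, ps = ps,
                           family = family, maximum = TRUE, tol = 1e-10)
    shape <- opt$maximum
    edge <- min(shape - shape_bracket[1], shape_bracket[2] - shape) <
      1e-4 * diff(shape_bracket)
    if (edge) {
      converged <- FALSE
      warning("shape estimate sits at the search-bracket edge; ",
              "treat this fit as non-converged.", call. = FALSE)
    }
    # profile-likelihood curvature -> standard error of the shape
    h <- max(1e-5, abs(shape) * 1e-4)
    d2 <- (profile_loglik(shape + h, ps, family) -
             2 * opt$objective +
             profile_loglik(shape - h, ps, family)) / h^2
    shape_se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
    if (family == "gompertz" && shape < 0 && converged) {
      warning("fitted Gompertz shape is negative: the hazard decays and ",
              "survival quantiles beyond the mortality plateau are undefined.",
              call. = FALSE)
    }
  }

  sh <- if (family == "exponential") 0 else shape
  rates <- profile_rates(sh, ps, family)
  # at the profiled rates (deaths / generalised exposure) the log-likelihood
  # collapses to the profile value exactly, zero-death groups included
  ll <- profile_loglik(sh, ps, family)
  k <- length(rates) + as.integer(family != "exponential")
  n <- nrow(rec)
  beta_all <- log(rates)
  out <- structure(list(
    family = family,
    shape = shape,
    shape_se = shape_se,
    rates = rates,
    beta0 = beta_all[[1]],
    beta = beta_all[-1] - beta_all[[1]],
    loglik = ll,
    n_params = k,
    aic = -2 * ll + 2 * k,
    bic = -2 * ll + k * log(n),
    n = n,
    n_events = sum(rec$event),
    converged = converged,
    horizon = max(rec$time_years),
    source = "mle"
  ), class = "parametric_fit")
  out
}

#' @export
print.parametric_fit <- function(x, ...) {
  cat(sprintf("<parametric_fit: %s, %d groups, n = %d (%d deaths)>\n",
              x$family, length(x$rates), x$n, x$n_events))
  if (!is.na(x$shape)) {
    cat(sprintf("  shared shape: %.5f (se %.5f)\n", x$shape, x$shape_se))
  }
  cat(sprintf("  loglik %.2f | AIC %.1f | BIC %.1f | converged: %s\n",
              x$loglik, x$aic, x$bic, x$converged))
  invisible(x)
}

#' Compare parametric survival families by information criteria
#'
#' Fits each requested family to the same cohort and tabulates
#' log-likelihood, AIC (\eqn{-2\ell + 2k}) and BIC (\eqn{-2\ell + k\ln n}),
#' ranked by AIC. A family whose fit fails is kept in the table with `NA`
#' values and the error message, rather than aborting the others.
#'
#' @inheritParams fit_parametric
#' @param families Character vector of families to fit.
#' @return A tibble with one row per family: `family`, `loglik`, `n_params`,
#'   `aic`, `bic`, `rank` (1 = lowest AIC), `error`.
#' @export
compare_families <- function(data,
                             families = c("gompertz", "weibull", "exponential")) {
  fits <- purrr::map(families, function(f) {
    tryCatch(fit_parametric(data, family = f),
             error = function(e) conditionMessage(e))
  })
  rows <- purrr::map2(families, fits, function(f, fit) {
    if (is.character(fit)) {
      tibble::tibble(family = f, loglik = NA_real_, n_params = NA_integer_,
                     aic = NA_real_, bic = NA_real_, error = fit)
    } else {
      tibble::tibble(family = f, loglik = fit$loglik,
                     n_params = as.integer(fit$n_params),
                     aic = fit$aic, bic = fit$bic, error = NA_character_)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$rank <- rank(out$aic, na.last = "keep")
  dplyr::arrange(out, .data$rank)
}
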