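#' Predicted survival quantiles (life expectancy) per risk group
#'
#' Inverts a fitted (or reconstructed) Gompertz model at the requested
#' mortality fractions for each risk group: the time to 50% mortality is the
#' group's median life expectancy, with times to 25% and 75% mortality
#' bracketing the central half of individual experience. Quantiles beyond the
#' follow-up horizon the model was fitted to rely on extrapolating the
#' exponential hazard growth and are flagged `extrapolated`.
#'
#' @param fit A `parametric_fit` (Gompertz or exponential family; a Weibull
#'   proportional-hazards fit is also invertible and supported).
#' @param groups Groups to predict for; default all groups in the fit.
#' @param probs Mortality fractions; default `c(0.25, 0.5, 0.75)`.
#' @param horizon Validated follow-up horizon in years used for the
#'   `extrapolated` flag; defaults to the fit's own maximum follow-up.
#' @return A tibble with one row per group: `group`, one column per quantile
#'   (`t25`, `t50`, `t75` for the defaults), and `extrapolated` (`TRUE` when
#'   any requested quantile exceeds the horizon).
#' @examples
#' fit <- reconstruct_gompertz(published_le_quantiles())
#' predict_life_expectancy(fit)
#' @export
predict_life_expectancy <- function(fit, groups = NULL,
                                    probs = c(0.25, 0.5, 0.75),
                                    horizon = NULL) {
  stopifnot(inherits(fit, "parametric_fit"))
  if (is.null(groups)) groups <- names(fit$rates)
  groups <- as.character(as_group_factor(groups))
  miss <- setdiff(groups, names(fit$rates))
  if (length(miss) > 0) {
    stop("group(s) absent from the fit: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(horizon)) horizon <- fit$horizon
  qmat <- vapply(probs, function(p) {
    model_quantile(fit, p, groups)
  }, numeric(length(groups)))
  qmat <- matrix(qmat, nrow = length(groups),
                 dimnames = list(NULL, paste0("t", round(100 * probs))))
  out <- tibble::tibble(group = as_group_factor(groups))
  out <- dplyr::bind_cols(out, tibble::as_tibble(qmat))
  out$extrapolated <- apply(qmat, 1, max) > horizon
  out
}

# quantile of one family's survival distribution at mortality fraction p;
# zero-rate groups (no observed deaths) map to Inf
model_quantile <- function(fit, p, groups) {
  lam <- fit$rates[groups]
  out <- rep(Inf, length(lam))
  ok <- lam > 0
  if (any(ok)) out[ok] <- model_quantile_pos(fit, p, lam[ok])
  out
}

model_quantile_pos <- function(fit, p, lam) {
  switch(fit$family,
    gompertz = gompertz_quantile(p, lam, fit$shape),
    exponential = -log1p(-p) / lam,
    weibull = (-log1p(-p) / lam)^(1 / fit$shape)
  )
}

# survival probability under the fitted model, vectorised over t
model_survival <- function(fit, t, group) {
  lam <- unname(fit$rates[as.character(as_group_factor(group))])
  switch(fit$family,
    gompertz = gompertz_survival(t, pmax(lam, .Machine$double.xmin), fit$shape),
    exponential = exp(-lam * t),
    weibull = exp(-lam * t^fit$shape)
  )
}

#' Bootstrap a grouped survival fit
#'
#' Resamples individuals with replacement, refits the model on each
#' replicate, and collects per-group survival quantiles. The replicate sets
#' feed percentile confidence intervals ([ci_from_bootstrap()]) and
#' individual-level prediction intervals ([prediction_interval()]).
#' Replicates whose fit fails (or that lose a group entirely) contribute `NA`
#' for the affected groups and are counted; more than 10% failures raises a
#' warning.
#'
#' @inheritParams fit_parametric
#' @param B Number of bootstrap replicates (at least 2; 1000 in the published
#'   analysis).
#' @param seed Integer seed; the only source of randomness, recorded in the
#'   result.
#' @param probs Mortality fractions collected per replicate.
#' @return An object of class `le_bootstrap`: list with `fit` (the full-data
#'   fit), `replicates` (tibble: `replicate`, `group`, `shape`, `rate`, one
#'   column per quantile), `B`, `n_failed`, `seed`.
#' @export
bootstrap_le <- function(data, B = 1000, seed = 1,
                         family = "gompertz",
                         probs = c(0.25, 0.5, 0.75)) {
  if (B < 2) stop("`B` must be at least 2 bootstrap replicates.", call. = FALSE)
  if (B < 100) {
    warning("fewer than 100 bootstrap replicates gives unstable percentile ",
            "intervals.", call. = FALSE)
  }
  rec <- as_survival_records(data)
  fit <- fit_parametric(rec, family = family)
  n <- nrow(rec)
  qnames <- paste0("t", round(100 * probs))
  set.seed(seed)
  reps <- purrr::map(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    rb <- tryCatch(
      suppressWarnings(fit_parametric(rec[idx, , drop = FALSE],
                                      family = family)),
      error = function(e) NULL
    )
    if (is.null(rb)) return(NULL)
    grp <- names(rb$rates)
    qs <- vapply(probs, function(p) {
      out <- rep(NA_real_, length(grp))
      ok <- rb$rates > 0
      out[ok] <- tryCatch(model_quantile(rb, p, grp[ok]),
                          error = function(e) rep(NA_real_, sum(ok)))
      out
    }, numeric(length(grp)))
    qs <- matrix(qs, nrow = length(grp), dimnames = list(NULL, qnames))
    dplyr::bind_cols(
      tibble::tibble(replicate = b, group = as_group_factor(grp),
                     shape = if (is.na(rb$shape)) 0 else rb$shape,
                     rate = unname(rb$rates)),
      tibble::as_tibble(qs)
    )
  })
  n_failed <- sum(purrr::map_lgl(reps, is.null))
  if (n_failed > 0.1 * B) {
    warning(n_failed, " of ", B, " bootstrap replicates failed to fit.",
            call. = FALSE)
  }
  structure(list(
    fit = fit,
    replicates = dplyr::bind_rows(reps),
    B = B,
    n_failed = n_failed,
    probs = probs,
    seed = seed
  ), class = "le_bootstrap")
}

#' @export
print.le_bootstrap <- function(x, ...) {
  cat(sprintf("<le_bootstrap: %d replicates (%d failed), seed %d, %s fit>\n",
              x$B, x$n_failed, x$seed, x$fit$family))
  invisible(x)
}

#' Percentile confidence intervals from bootstrap replicates
#'
#' Percentile-method confidence intervals for each group's survival
#' quantiles: the interval endpoints are empirical quantiles of the bootstrap
#' replicate values. These bound the *population* quantile (e.g. the group's
#' true median life expectancy), not an individual's survival time — see
#' [prediction_interval()] for the latter.
#'
#' @param boot An [bootstrap_le()] result.
#' @param level Confidence level (default 0.95).
#' @return Tibble: `group`, `quantile` (`"t25"`, ...), `estimate` (full-data
#'   point estimate), `conf_low`, `conf_high`, `n_boot`.
#' @export
ci_from_bootstrap <- function(boot, level = 0.95) {
  stopifnot(inherits(boot, "le_bootstrap"))
  qnames <- paste0("t", round(100 * boot$probs))
  point <- predict_life_expectancy(boot$fit, probs = boot$probs) |>
    tidyr::pivot_longer(dplyr::all_of(qnames), names_to = "quantile",
                        values_to = "estimate")
  a <- (1 - level) / 2
  long <- tidyr::pivot_longer(boot$replicates, dplyr::all_of(qnames),
                              names_to = "quantile", values_to = "value")
  ci <- long |>
    dplyr::group_by(.data$group, .data$quantile) |>
    dplyr::summarise(
      conf_low = stats::quantile(.data$value, a, na.rm = TRUE, names = FALSE),
      conf_high = stats::quantile(.data$value, 1 - a, na.rm = TRUE,
                                  names = FALSE),
      n_boot = sum(!is.na(.data$value)),
      .groups = "drop"
    )
  dplyr::left_join(point[c("group", "quantile", "estimate")], ci,
                   by = c("group", "quantile"))
}

#' Individual-level prediction intervals
#'
#' A central prediction interval for one person's survival time, combining
#' sampling uncertainty in the fitted parameters with between-individual
#' variability: for every bootstrap replicate, `draws` individual survival
#' times are simulated from that replicate's fitted distribution for the
#' group, and the interval is taken as the central `level` quantiles of the
#' pooled draws. With no sampling uncertainty this collapses to the model's
#' own `[t25, t75]` interval (for `level = 0.5`) up to Monte-Carlo error.
#'
#' @param boot An [bootstrap_le()] result.
#' @param level Central coverage (default 0.50, the published choice).
#' @param draws Individual survival times drawn per replicate and group.
#' @param seed Seed for the individual draws (independent of the bootstrap
#'   seed so the replicate set is reusable).
#' @return Tibble: `group`, `pi_low`, `pi_high`, `level`, `n_draws`.
#' @export
prediction_interval <- function(boot, level = 0.5, draws = 100,
                                seed = boot$seed + 1L) {
  stopifnot(inherits(boot, "le_bootstrap"))
  reps <- dplyr::filter(boot$replicates, !is.na(.data$rate), .data$rate > 0)
  if (nrow(reps) == 0) stop("no usable bootstrap replicates.", call. = FALSE)
  a <- (1 - level) / 2
  set.seed(seed)
  u <- stats::runif(nrow(reps) * draws)
  times <- gompertz_quantile(
    u,
    rate = rep(reps$rate, each = draws),
    shape = rep(reps$shape, each = draws)
  )
  pooled <- tibble::tibble(group = rep(reps$group, each = draws), time = times)
  pooled |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      pi_low = stats::quantile(.data$time, a, names = FALSE),
      pi_high = stats::quantile(.data$time, 1 - a, names = FALSE),
      level = level,
      n_draws = dplyr::n(),
      .groups = "drop"
    )
}

#' Full life-expectancy table with confidence and prediction intervals
#'
#' One-call wrapper: fits the Gompertz model, bootstraps it, and assembles
#' the per-group table of survival quantiles with 95% confidence intervals
#' and the 50% prediction interval, in the layout of the published
#' calculator.
#'
#' @inheritParams bootstrap_le
#' @param conf_level Confidence level for the quantile CIs.
#' @param pi_level Central coverage of the prediction interval.
#' @param horizon Validated follow-up horizon (years) for the
#'   `extrapolated` flag.
#' @return Tibble: `group`, `t25`, `t50`, `t75`, `*_low`/`*_high` 95% CI
#'   bounds per quantile, `pi_low`, `pi_high`, `extrapolated`, plus
#'   attributes `seed` and `B`.
#' @export
life_expectancy_table <- function(data, B = 1000, seed = 1,
                                  conf_level = 0.95, pi_level = 0.5,
                                  horizon = NULL) {
  boot <- bootstrap_le(data, B = B, seed = seed)
  assemble_le_table(boot, conf_level = conf_level, pi_level = pi_level,
                    horizon = horizon)
}

assemble_le_table <- function(boot, conf_level = 0.95, pi_level = 0.5,
                              horizon = NULL) {
  point <- predict_life_expectancy(boot$fit, probs = boot$probs,
                                   horizon = horizon)
  ci <- ci_from_bootstrap(boot, level = conf_level) |>
    tidyr::pivot_wider(id_cols = "group", names_from = "quantile",
                       values_from = c("conf_low", "conf_high"),
                       names_glue = "{quantile}_{.value}")
  names(ci) <- sub("_conf_", "_", names(ci))
  pi <- prediction_interval(boot, level = pi_level)
  out <- point |>
    dplyr::left_join(ci, by = "group") |>
    dplyr::left_join(pi[c("group", "pi_low", "pi_high")], by = "group") |>
    dplyr::relocate("extrapolated", .after = dplyr::last_col())
  attr(out, "seed") <- boot$seed
  attr(out, "B") <- boot$B
  out
}

#' Re-calibrate a Gompertz model from a published quantile table
#'
#' Recovers group-level Gompertz parameters from a table of published
#' survival quantiles — the re-calibration route when individual-level data
#' are unavailable. A single shared shape is estimated by least squares on
#' the quantile-ratio equation: for each group with two quantiles
#' \eqn{(t_{p_1}, t_{p_2})}, the shape must satisfy
#' \deqn{\frac{e^{\gamma t_{p_2}} - 1}{e^{\gamma t_{p_1}} - 1}
#'       = \frac{\ln(1-p_2)}{\ln(1-p_1)},}
#' independent of the group's rate; the shape minimising the summed squared
#' log-ratio residuals over all supplied groups is used (each group weighted
#' equally on that scale, so heavily rounded short-time rows do not
#' dominate). Each group's rate is then solved exactly from its median:
#' \eqn{\lambda_g = \gamma \ln 2 / (e^{\gamma t_{50,g}} - 1)}.
#'
#' On a noiseless table generated from a true shared-shape Gompertz model the
#' reconstruction is exact (up to optimiser tolerance).
#'
#' @param table Data frame with columns `group`, `t25`, `t50` (years; an
#'   optional `t75` column is accepted and ignored by the estimator so that
#'   published three-quantile tables can be passed as-is).
#' @param shape_bracket Search interval for the shared shape.
#' @return A `parametric_fit` (family `"gompertz"`, `source =
#'   "reconstructed"`); no likelihood-based fields (`loglik`, `aic`, `bic`
#'   are `NA`).
#' @examples
#' fit <- reconstruct_gompertz(published_le_quantiles())
#' fit$shape  # about 0.112 per year: hazard doubling every ~6.2 years
#' @export
reconstruct_gompertz <- function(table, shape_bracket = c(1e-4, 1)) {
  stopifnot(is.data.frame(table))
  need <- c("group", "t25", "t50")
  absent <- setdiff(need, names(table))
  if (length(absent) > 0) {
    stop("quantile table must have column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  grp <- as_group_factor(table$group)
  t25 <- as.numeric(table$t25)
  t50 <- as.numeric(table$t50)
  bad <- !is.finite(t25) | !is.finite(t50) | t25 <= 0 | t50 <= t25
  if (any(bad)) {
    stop("non-increasing or non-positive quantiles for group(s): ",
         paste(as.character(grp[bad]), collapse = ", "), call. = FALSE)
  }
  target <- log(log(0.5) / log(0.75)) # log cumulative-hazard ratio t50 vs t25
  obj <- function(g) {
    sum((log(expm1(g * t50) / expm1(g * t25)) - target)^2)
  }
  opt <- stats::optimize(obj, shape_bracket, tol = 1e-12)
  shape <- opt$minimum
  rates <- shape * log(2) / expm1(shape * t50)
  names(rates) <- as.character(grp)
  beta_all <- log(rates)
  structure(list(
    family = "gompertz",
    shape = shape,
    shape_se = NA_real_,
    rates = rates,
    beta0 = beta_all[[1]],
    beta = beta_all[-1] - beta_all[[1]],
    loglik = NA_real_,
    n_params = length(rates) + 1L,
    aic = NA_real_,
    bic = NA_real_,
    n = NA_integer_,
    n_events = NA_integer_,
    converged = TRUE,
    horizon = 10,
    source = "reconstructed"
  ), class = "parametric_fit")
}

#' Solve a Gompertz rate from one published quantile
#'
#' Given a shared shape, the rate that places mortality fraction `p` exactly
#' at time `t`: \eqn{\lambda = -\gamma \ln(1-p) / (e^{\gamma t} - 1)}.
#' Useful for predicting a group's remaining quantiles from its published
#' median and a shape estimated on other groups.
#'
#' @param t Time in years at which mortality fraction `p` is reached.
#' @param p Mortality fraction in (0, 1).
#' @param shape Shared Gompertz shape.
#' @return The rate \eqn{\lambda} (per year).
#' @export
gompertz_rate_from_quantile <- function(t, p, shape) {
  check_time(t)
  if (any(p <= 0) || any(p >= 1)) stop("`p` must be in (0, 1).", call. = FALSE)
  y <- -log1p(-p)
  ifelse(abs(shape * t) < 1e-9, y / t, shape * y / expm1(shape * t))
}
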