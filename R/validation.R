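#' Kaplan-Meier survival curves per risk group
#'
#' Product-limit estimate of each group's survival curve under right
#' censoring, computed with [survival::survfit()]. Subjects censored at an
#' event time are kept at risk for that event time (the standard
#' convention).
#'
#' @inheritParams fit_parametric
#' @return A tibble of class `km_curves`: `group`, `time` (years), `n_risk`,
#'   `n_event`, `n_censor`, `surv` (stepwise non-increasing, starting below 1
#'   only after the first event).
#' @seealso [km_quantile()] for median/quartile lookup with "not reached"
#'   semantics.
#' @export
km_curves <- function(data) {
  rec <- as_survival_records(data)
  rec$group <- droplevels(rec$group)
  sf <- survival::survfit(
    survival::Surv(time_years, event) ~ group,
    data = rec
  )
  if (nlevels(rec$group) == 1) {
    strata_grp <- rep(levels(rec$group), length(sf$time))
  } else {
    strata_grp <- rep(sub("^group=", "", names(sf$strata)), sf$strata)
  }
  out <- tibble::tibble(
    group = as_group_factor(strata_grp),
    time = sf$time,
    n_risk = sf$n.risk,
    n_event = sf$n.event,
    n_censor = sf$n.censor,
    surv = sf$surv
  )
  class(out) <- c("km_curves", class(out))
  out
}

#' Survival quantile lookup on a Kaplan-Meier curve
#'
#' Time at which the observed curve first drops to `1 - p` or below, per
#' group. When the curve never reaches the target within follow-up the value
#' is `NA` with `not_reached = TRUE` — rendered as ">horizon" in published
#' tables.
#'
#' @param km A [km_curves()] tibble.
#' @param p Mortality fraction (default 0.5: observed median survival).
#' @return Tibble: `group`, `p`, `time`, `not_reached`.
#' @export
km_quantile <- function(km, p = 0.5) {
  stopifnot(inherits(km, "km_curves"), p > 0, p < 1)
  km |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      p = p,
      time = suppressWarnings(min(.data$time[.data$surv <= 1 - p])),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      not_reached = !is.finite(.data$time),
      time = dplyr::if_else(.data$not_reached, NA_real_, .data$time)
    )
}

# observed survival at one horizon per group, carried forward from the last
# step at or before the horizon (1 before any event)
km_surv_at <- function(km, horizon, groups = levels(km$group)) {
  vapply(groups, function(g) {
    sub <- km[km$group == g & km$time <= horizon, ]
    if (nrow(sub) == 0) 1 else sub$surv[[nrow(sub)]]
  }, numeric(1))
}

#' Harrell's concordance for a censored cohort
#'
#' Probability, over usable subject pairs, that the subject with the higher
#' risk score dies first. A pair is usable when the shorter follow-up time
#' ends in death (a death at time *t* is also comparable with a censoring at
#' exactly *t*); pairs with tied event times are excluded; pairs with tied
#' scores count 1/2. Computed by a single sweep over event times with
#' per-score tallies, so cohorts of tens of thousands with a handful of
#' score levels are handled in milliseconds.
#'
#' @inheritParams fit_parametric
#' @param score Risk score per subject (higher = higher mortality risk).
#'   Defaults to the numeric point group, the calculator's own predictor;
#'   any strictly monotone transform gives the same concordance.
#' @return One-row tibble: `concordance`, `concordant`, `discordant`,
#'   `tied_score`, `n_pairs` (usable pairs).
#' @export
harrells_c <- function(data, score = NULL) {
  rec <- as_survival_records(data)
  if (is.null(score)) {
    score <- as.numeric(as_group_factor(rec$group))
  }
  stopifnot(length(score) == nrow(rec))
  if (any(is.na(score))) stop("`score` may not be missing.", call. = FALSE)

  sc <- factor(score, levels = sort(unique(score)))
  ut <- sort(unique(rec$time_years))
  ti <- match(rec$time_years, ut)
  K <- nlevels(sc)
  G <- length(ut)
  # counts of subjects by (time index, score level), split by event status
  dead <- table(factor(ti[rec$event], levels = seq_len(G)), sc[rec$event])
  cens <- table(factor(ti[!rec$event], levels = seq_len(G)), sc[!rec$event])
  dead <- matrix(dead, nrow = G); cens <- matrix(cens, nrow = G)
  all_ <- dead + cens
  # later[k, s]: subjects with time strictly greater than ut[k], by score
  later <- apply(all_, 2, function(col) rev(cumsum(rev(col)))) - all_
  later <- matrix(later, nrow = G)
  comp <- later + cens            # comparators for a death at ut[k]
  # lower[k, s]: comparators at ut[k] with score strictly below level s
  if (K == 1) {
    lower <- matrix(0, nrow = G, ncol = 1)
  } else {
    lower <- cbind(0, t(apply(comp, 1, cumsum))[, -K, drop = FALSE])
  }
  concordant <- sum(dead * lower)
  tied_score <- sum(dead * comp)  # elementwise: same-score comparators
  usable <- sum(rowSums(dead) * rowSums(comp))
  if (usable == 0) {
    stop("no usable pairs: concordance is undefined.", call. = FALSE)
  }
  discordant <- usable - concordant - tied_score
  tibble::tibble(
    concordance = (concordant + 0.5 * tied_score) / usable,
    concordant = concordant,
    discordant = discordant,
    tied_score = tied_score,
    n_pairs = usable
  )
}

#' Fixed-horizon Hosmer-Lemeshow calibration test
#'
#' Compares observed and model-expected deaths by a fixed horizon across the
#' risk groups. Observed deaths respect censoring: per group,
#' \eqn{O_g = n_g (1 - \hat S_{KM,g}(h))} from the Kaplan-Meier estimate;
#' expected deaths come from the fitted model,
#' \eqn{E_g = n_g (1 - S_{model,g}(h))}. The statistic is
#' \deqn{X^2 = \sum_g \frac{(O_g - E_g)^2}{E_g (1 - E_g/n_g)},}
#' referred to a chi-square with \eqn{G - 2} degrees of freedom when the
#' model was fitted to the same data (`df_style = "development"`) or \eqn{G}
#' when the model is external to the cohort (`"external"`). Groups with
#' expected deaths below 1 are merged into the adjacent lower-risk group with
#' a warning.
#'
#' @inheritParams fit_parametric
#' @param fit A `parametric_fit` covering every group in `data`.
#' @param horizon Horizon in years (must lie within follow-up).
#' @param df_style `"development"` (df = G-2) or `"external"` (df = G).
#' @return One-row tibble: `horizon`, `statistic`, `df`, `p_value`,
#'   `n_groups` (after merging), `n_merged`.
#' @export
hosmer_lemeshow <- function(data, fit, horizon,
                            df_style = c("development", "external")) {
  df_style <- match.arg(df_style)
  stopifnot(inherits(fit, "parametric_fit"))
  rec <- as_survival_records(data)
  if (horizon <= 0 || horizon > max(rec$time_years)) {
    stop("`horizon` must lie within the cohort's follow-up.", call. = FALSE)
  }
  rec$group <- droplevels(rec$group)
  groups <- levels(rec$group)
  miss <- setdiff(groups, names(fit$rates))
  if (length(miss) > 0) {
    stop("group(s) absent from the fit: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  km <- km_curves(rec)
  n_g <- as.numeric(table(rec$group))
  obs <- n_g * (1 - km_surv_at(km, horizon, groups))
  expd <- n_g * (1 - model_survival(fit, horizon, groups))

  # merge low-expectation groups into their lower-risk neighbour
  n_merged <- 0L
  while (length(expd) > 1 && any(expd < 1)) {
    i <- which(expd < 1)[1]
    j <- if (i == 1) 2L else i - 1L
    expd[j] <- expd[j] + expd[i]
    obs[j] <- obs[j] + obs[i]
    n_g[j] <- n_g[j] + n_g[i]
    expd <- expd[-i]; obs <- obs[-i]; n_g <- n_g[-i]
    n_merged <- n_merged + 1L
  }
  if (n_merged > 0) {
    warning(n_merged, " group(s) with expected deaths < 1 merged into a ",
            "neighbouring group.", call. = FALSE)
  }
  G <- length(expd)
  df <- if (df_style == "development") G - 2L else G
  if (df <= 0) {
    stop("too few groups for a calibration test (df <= 0).", call. = FALSE)
  }
  statistic <- sum((obs - expd)^2 / (expd * (1 - expd / n_g)))
  tibble::tibble(
    horizon = horizon,
    statistic = statistic,
    df = as.integer(df),
    p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
    n_groups = as.integer(G),
    n_merged = n_merged
  )
}

#' Predicted-vs-observed survival curves in long format
#'
#' Pairs each group's model-predicted survival curve with its observed
#' Kaplan-Meier curve on a common time grid, truncated at the follow-up
#' horizon — the plot data behind the calibration figures.
#'
#' @param fit A `parametric_fit`.
#' @param km A [km_curves()] tibble sharing the fit's groups.
#' @param horizon Truncation horizon in years.
#' @param step Grid spacing (years) for the predicted curve.
#' @return Tibble: `group`, `time`, `curve` (`"predicted"`/`"observed"`),
#'   `surv`.
#' @export
export_curves <- function(fit, km, horizon = 10, step = 0.25) {
  stopifnot(inherits(fit, "parametric_fit"), inherits(km, "km_curves"))
  groups <- intersect(levels(droplevels(km$group)), names(fit$rates))
  if (length(groups) == 0) {
    stop("fit and Kaplan-Meier curves share no groups.", call. = FALSE)
  }
  grid <- seq(0, horizon, by = step)
  pred <- purrr::map(groups, function(g) {
    tibble::tibble(group = g, time = grid, curve = "predicted",
                   surv = model_survival(fit, grid, rep(g, length(grid))))
  }) |> dplyr::bind_rows()
  obs <- km |>
    dplyr::filter(.data$group %in% groups, .data$time <= horizon) |>
    dplyr::transmute(group = as.character(.data$group), time = .data$time,
                     curve = "observed", surv = .data$surv)
  out <- dplyr::bind_rows(pred, obs)
  out$group <- as_group_factor(out$group)
  dplyr::arrange(out, .data$group, .data$curve, .data$time)
}

#' Full validation report for a fitted calculator
#'
#' Bundles the published diagnostics in one object: Harrell's concordance of
#' the point score, Hosmer-Lemeshow calibration at each horizon, and
#' predicted-vs-observed curve data.
#'
#' @inheritParams hosmer_lemeshow
#' @param horizons Horizons (years) for the calibration tests.
#' @param label Cohort label carried into the report.
#' @return An object of class `validation_report`: list with `label`,
#'   `harrells_c` (one-row tibble), `hosmer_lemeshow` (tibble, one row per
#'   horizon), `curves` (long tibble), `df_style`.
#' @export
validate_fit <- function(data, fit, horizons = c(5, 8, 10),
                         df_style = c("development", "external"),
                         label = "cohort") {
  df_style <- match.arg(df_style)
  rec <- as_survival_records(data)
  km <- km_curves(rec)
  hl <- purrr::map(horizons, function(h) {
    hosmer_lemeshow(rec, fit, horizon = h, df_style = df_style)
  }) |> dplyr::bind_rows()
  structure(list(
    label = label,
    harrells_c = harrells_c(rec),
    hosmer_lemeshow = hl,
    curves = export_curves(fit, km, horizon = max(horizons)),
    df_style = df_style
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report: %s>\n", x$label))
  cat(sprintf("  Harrell's c: %.3f (%d usable pairs)\n",
              x$harrells_c$concordance, x$harrells_c$n_pairs))
  for (i in seq_len(nrow(x$hosmer_lemeshow))) {
    r <- x$hosmer_lemeshow[i, ]
    cat(sprintf("  Hosmer-Lemeshow at %gy: X2 = %.2f, df = %d, p = %.3g\n",
                r$horizon, r$statistic, r$df, r$p_value))
  }
  invisible(x)
}
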