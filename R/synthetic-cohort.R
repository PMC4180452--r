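#' Specify a synthetic cohort with known truth
#'
#' A cohort specification fixes everything needed to simulate an HRS-like
#' survival cohort: how many subjects fall in each of the 15 risk-point
#' groups, the true group-level Gompertz model (shared shape, per-group
#' rates), and the censoring mechanism (administrative horizon plus an
#' optional uniform-dropout fraction). [sample_cohort()] then draws survival
#' times by inverse-CDF from each group's Gompertz distribution.
#'
#' Group membership may be given as exact `group_counts` (the printed cohort
#' composition; used verbatim) or as `group_probs` (multinomial sampling).
#' `mode = "factor"` instead draws the 12 risk items independently from their
#' marginal prevalences and scores them with [score_profiles()]; because only
#' marginals are emulated, the joint score distribution differs from the
#' printed one, so `"score"` mode is the default.
#'
#' @param group_counts Integer vector of 15 per-group counts, or `NULL`.
#' @param group_probs Numeric vector of 15 probabilities summing to 1, or
#'   `NULL` (required when sampling with `n` different from the counts).
#' @param shape True shared Gompertz shape (per year).
#' @param rates True per-group rates (per year), length 15 (or named by
#'   group).
#' @param horizon Administrative censoring horizon in years (default 10, the
#'   development follow-up).
#' @param dropout Fraction of subjects given an additional uniform(0,
#'   horizon) dropout-censoring time (default 0).
#' @param mode `"score"` (default) or `"factor"`; see Details.
#' @param prevalences For `"factor"` mode, a cohort name passed to the
#'   built-in prevalence tables (`"development"`, `"validation"`, `"elsa"`).
#' @return An object of class `cohort_spec`.
#' @seealso [hrs_cohort_spec()] for the built-in published specifications.
#' @export
cohort_spec <- function(group_counts = NULL, group_probs = NULL,
                        shape, rates, horizon = 10, dropout = 0,
                        mode = c("score", "factor"),
                        prevalences = "development") {
  mode <- match.arg(mode)
  if (is.null(group_counts) && is.null(group_probs) && mode == "score") {
    stop("supply `group_counts` or `group_probs`.", call. = FALSE)
  }
  if (!is.null(group_probs)) {
    if (length(group_probs) != 15 || any(group_probs < 0) ||
        abs(sum(group_probs) - 1) > 1e-9) {
      stop("`group_probs` must be 15 non-negative values summing to 1.",
           call. = FALSE)
    }
  }
  if (!is.null(group_counts) && length(group_counts) != 15) {
    stop("`group_counts` must have one count per risk group (15).",
         call. = FALSE)
  }
  if (length(rates) == 1) rates <- rep(rates, 15)
  if (is.null(names(rates))) names(rates) <- group_levels()
  if (any(rates <= 0) || !is.finite(shape)) {
    stop("true `rates` must be positive and `shape` finite.", call. = FALSE)
  }
  if (horizon <= 0) stop("`horizon` must be positive.", call. = FALSE)
  if (dropout < 0 || dropout > 1) stop("`dropout` must be in [0, 1].",
                                       call. = FALSE)
  structure(list(
    group_counts = if (is.null(group_counts)) NULL else as.integer(group_counts),
    group_probs = group_probs,
    shape = shape,
    rates = rates,
    horizon = horizon,
    dropout = dropout,
    mode = mode,
    prevalences = prevalences
  ), class = "cohort_spec")
}

#' Built-in cohort specifications matching the published cohorts
#'
#' Returns a [cohort_spec()] with the printed per-group subject counts of the
#' named cohort (HRS development n = 11701, HRS validation n = 8009, ELSA
#' validation n = 7042) and, by default, the group-level Gompertz model
#' reconstructed from the published quantile table
#' ([reconstruct_gompertz()] on [published_le_quantiles()]).
#'
#' @param cohort `"development"`, `"validation"` or `"elsa"`.
#' @param horizon Administrative censoring horizon; defaults to the cohort's
#'   published follow-up (10 years for HRS, 8 for ELSA).
#' @return A `cohort_spec`.
#' @examples
#' spec <- hrs_cohort_spec("development")
#' sum(spec$group_counts)  # 11701
#' @export
hrs_cohort_spec <- function(cohort = c("development", "validation", "elsa"),
                            horizon = NULL) {
  cohort <- match.arg(cohort)
  if (is.null(horizon)) horizon <- if (cohort == "elsa") 8 else 10
  model <- reconstruct_gompertz(published_le_quantiles())
  cohort_spec(
    group_counts = cohort_group_counts(cohort)$count,
    shape = model$shape,
    rates = model$rates,
    horizon = horizon,
    prevalences = cohort
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  n <- if (!is.null(x$group_counts)) sum(x$group_counts) else NA
  cat(sprintf("<cohort_spec: %s mode, n = %s, shape %.4f, horizon %gy%s>\n",
              x$mode, format(n), x$shape, x$horizon,
              if (x$dropout > 0) sprintf(", dropout %g", x$dropout) else ""))
  invisible(x)
}

#' Simulate a survival cohort from a specification
#'
#' Draws one synthetic cohort: group membership from the spec's exact counts
#' (or multinomially from its probabilities), a latent death time per subject
#' by inverse-CDF from the group's Gompertz distribution, and right censoring
#' at the administrative horizon (and, if specified, at a uniform dropout
#' time). Fully reproducible from `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param n Cohort size; defaults to the sum of the spec's counts. When `n`
#'   differs from that sum, counts are rescaled to probabilities and
#'   membership is drawn multinomially.
#' @param seed Integer seed (the only randomness source).
#' @return A tibble of survival records: `id`, `group`, `points`,
#'   `time_years`, `event`, with attributes `seed` and `latent_horizon`.
#' @examples
#' cohort <- sample_cohort(hrs_cohort_spec("development"), n = 1000, seed = 42)
#' table(cohort$event)
#' @export
sample_cohort <- function(spec, n = NULL, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)

  if (spec$mode == "factor") {
    if (is.null(n)) stop("`n` is required in factor mode.", call. = FALSE)
    profiles <- sample_profiles(n, spec$prevalences)
    scored <- score_profiles(profiles)
    grp <- scored$group
    points <- scored$points
  } else {
    exact <- !is.null(spec$group_counts) &&
      (is.null(n) || n == sum(spec$group_counts))
    if (exact) {
      counts <- spec$group_counts
      n <- sum(counts)
      grp <- as_group_factor(rep(group_levels(), counts))
    } else {
      probs <- spec$group_probs
      if (is.null(probs)) probs <- spec$group_counts / sum(spec$group_counts)
      grp <- as_group_factor(sample(group_levels(), n, replace = TRUE,
                                    prob = probs))
    }
    points <- pmin(as.integer(grp) - 1L, 14L)
  }

  lam <- spec$rates[as.character(grp)]
  latent <- gompertz_quantile(stats::runif(n), lam, spec$shape)
  cens_time <- rep(spec$horizon, n)
  if (spec$dropout > 0) {
    drops <- stats::runif(n) < spec$dropout
    cens_time[drops] <- pmin(cens_time[drops],
                             stats::runif(sum(drops), 0, spec$horizon))
  }
  out <- tibble::tibble(
    id = seq_len(n),
    group = grp,
    points = points,
    time_years = pmin(latent, cens_time),
    event = latent <= cens_time
  )
  attr(out, "seed") <- seed
  attr(out, "true_shape") <- spec$shape
  out
}

# draw the 12 items independently from a cohort's marginal prevalences;
# age uniform within its band (85+ treated as 85-94)
sample_profiles <- function(n, cohort = "development") {
  prev_col <- paste0("prev_", cohort)
  bands <- age_band_points()
  items <- lee_item_points()
  n_cohort <- sum(bands[[prev_col]])
  band <- sample.int(nrow(bands), n, replace = TRUE,
                     prob = bands[[prev_col]] / n_cohort)
  upper <- ifelse(is.finite(bands$upper[band]), bands$upper[band], 94)
  age <- floor(stats::runif(n, bands$lower[band], upper + 1))
  out <- tibble::tibble(age_years = pmin(age, 110))
  for (i in seq_len(nrow(items))) {
    out[[items$item[i]]] <- stats::runif(n) < items[[prev_col]][i] / n_cohort
  }
  out
}
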