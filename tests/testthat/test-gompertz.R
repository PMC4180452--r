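test_that("hazard and survival have their closed-form values and limits", {
  expect_equal(gompertz_hazard(0, 0.01, 0.1), 0.01)
  expect_equal(gompertz_hazard(c(1, 5, 20), 0.02, 0), rep(0.02, 3))
  expect_equal(gompertz_hazard(10, 0.01, 0.1), 0.01 * exp(1))
  expect_equal(gompertz_survival(0, 0.3, 0.2), 1)
  expect_equal(gompertz_survival(10, 0.1, 0), exp(-1))
  expect_error(gompertz_hazard(1, -0.1, 0.1), "positive")
  expect_error(gompertz_survival(-1, 0.1, 0.1), "non-negative")
})

test_that("the small-shape branch agrees with exponential formulas to 1e-10", {
  t <- c(0.5, 3, 17, 60)
  for (shape in c(1e-12, -1e-12)) {
    expect_equal(gompertz_survival(t, 0.05, shape), exp(-0.05 * t),
                 tolerance = 1e-10)
    expect_equal(gompertz_quantile(c(0.25, 0.5, 0.9), 0.05, shape),
                 -log(1 - c(0.25, 0.5, 0.9)) / 0.05, tolerance = 1e-10)
  }
})

test_that("survival is strictly decreasing with S(0) = 1 and a vanishing tail", {
  set.seed(21)
  for (rep in 1:20) {
    rate <- runif(1, 1e-4, 0.05)       # demographically plausible baselines
    shape <- runif(1, 0, 0.15)
    t <- sort(runif(8, 0, 30))
    s <- gompertz_survival(t, rate, shape)
    expect_true(all(diff(s) < 0))
    expect_true(all(s > 0 & s <= 1))
    expect_lt(gompertz_survival(1e4, rate, max(shape, 1e-3)), 1e-12)
  }
})

test_that("survival at the reconstructed group-0 median is one half", {
  fit <- reconstruct_gompertz(published_le_quantiles())
  lam0 <- fit$rates[["0"]]
  expect_equal(lam0, 0.0015, tolerance = 0.05)
  expect_equal(gompertz_survival(35.4, lam0, fit$shape), 0.5,
               tolerance = 1e-3)
})

test_that("censored log-likelihood matches its closed forms and contracts", {
  d <- tibble::tibble(group = "0", time_years = 4.2, event = TRUE)
  expect_equal(survival_loglik(d, rates = c("0" = 1), shape = 0), -4.2)
  all_cens <- tibble::tibble(group = "0", time_years = c(1, 2), event = FALSE)
  expect_error(survival_loglik(all_cens, rates = c("0" = 1), shape = 0.1),
               "no observed deaths")
})

test_that("log-likelihood equals the quadrature cumulative-hazard oracle", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 40
    rate_by_group <- c("0" = runif(1, 0.005, 0.1), "5" = runif(1, 0.05, 0.4))
    shape <- runif(1, -0.05, 0.3)
    d <- tibble::tibble(
      group = sample(c("0", "5"), n, replace = TRUE),
      time_years = runif(n, 0.1, 15),
      event = runif(n) < 0.7
    )
    if (!any(d$event)) d$event[1] <- TRUE
    ll <- survival_loglik(d, rates = rate_by_group, shape = shape)
    oracle <- loglik_by_quadrature(d$time_years, d$event,
                                   rate_by_group[d$group], shape)
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("the MLE recovers known parameters and is a local maximum", {
  model <- reconstruct_gompertz(published_le_quantiles())
  spec <- cohort_spec(group_counts = cohort_group_counts("development")$count,
                      shape = model$shape, rates = model$rates, horizon = 10)
  cohort <- sample_cohort(spec, n = 20000, seed = 5)
  fit <- fit_parametric(cohort)
  expect_true(fit$converged)
  expect_lt(abs(fit$shape - model$shape), 0.1 * model$shape)

  # perturbing the shape or any rate around the optimum lowers the likelihood
  groups <- names(fit$rates)
  ll_hat <- survival_loglik(cohort, fit$rates, fit$shape)
  expect_equal(ll_hat, fit$loglik, tolerance = 1e-6)
  for (eps in c(-0.01, 0.01)) {
    expect_lt(survival_loglik(cohort, fit$rates, fit$shape * (1 + eps)),
              ll_hat)
    bumped <- fit$rates
    bumped[["5"]] <- bumped[["5"]] * (1 + eps)
    expect_lt(survival_loglik(cohort, bumped, fit$shape), ll_hat)
  }
})

test_that("constant-hazard data yields a shape within 2 SE of zero", {
  # a ~95%-probability event per draw, so require it on most of 5 cohorts
  set.seed(41)
  n <- 4000
  hits <- vapply(1:5, function(s) {
    grp <- sample(c("3", "8"), n, replace = TRUE)
    lam <- ifelse(grp == "3", 0.04, 0.12)
    latent <- stats::rexp(n, lam)
    d <- tibble::tibble(group = grp, time_years = pmin(latent, 10),
                        event = latent <= 10)
    fit <- fit_parametric(d)
    abs(fit$shape) < 2 * fit$shape_se
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("fit agrees with an independent Gompertz regression fit", {
  skip_if_not_installed("flexsurv")
  spec <- hrs_cohort_spec("development")
  cohort <- sample_cohort(spec, n = 3000, seed = 9)
  cohort <- dplyr::filter(cohort, group %in% c("2", "8", "14+"))
  fit <- fit_parametric(cohort)
  ref <- flexsurv::flexsurvreg(
    survival::Surv(time_years, event) ~ group,
    data = dplyr::mutate(cohort, group = droplevels(group)),
    dist = "gompertz"
  )
  expect_equal(fit$shape, ref$res["shape", "est"], tolerance = 1e-4)
  expect_equal(unname(fit$rates[["2"]]), ref$res["rate", "est"],
               tolerance = 1e-4)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected and zero-event groups warned about", {
  expect_error(fit_parametric(data.frame()), "column|empty")
  no_deaths <- tibble::tibble(group = "1", time_years = c(5, 7), event = FALSE)
  expect_error(fit_parametric(no_deaths), "no observed deaths")
  set.seed(61)
  latent <- rexp(50, 0.3)
  mixed <- tibble::tibble(
    group = c(rep("1", 50), rep("2", 5)),
    time_years = c(pmin(latent, 10), rep(10, 5)),
    event = c(latent <= 10, rep(FALSE, 5))
  )
  w <- capture_warnings(fit_parametric(mixed))
  expect_match(w, "no observed deaths", all = FALSE)
})

test_that("information criteria follow their closed forms and ranking", {
  spec <- hrs_cohort_spec("development")
  cohort <- sample_cohort(spec, n = 4000, seed = 3)
  tab <- compare_families(cohort)
  expect_setequal(tab$family, c("gompertz", "weibull", "exponential"))
  k <- ifelse(tab$family == "exponential", 15, 16)
  expect_equal(tab$aic, -2 * tab$loglik + 2 * k)
  expect_equal(tab$bic, -2 * tab$loglik + k * log(4000))
  expect_identical(tab$family[tab$rank == 1], "gompertz")
})

test_that("exponential-generated data keeps the exponential within 2 AIC", {
  set.seed(51)
  n <- 6000
  grp <- sample(c("4", "9"), n, replace = TRUE)
  lam <- ifelse(grp == "4", 0.05, 0.15)
  latent <- stats::rexp(n, lam)
  d <- tibble::tibble(group = grp, time_years = pmin(latent, 10),
                      event = latent <= 10)
  tab <- suppressWarnings(
    compare_families(d, families = c("gompertz", "exponential"))
  )
  aics <- setNames(tab$aic, tab$family)
  expect_lte(aics[["exponential"]], aics[["gompertz"]] + 2)
})

test_that("proportional hazards: group hazard ratios are constant in time", {
  fit <- reconstruct_gompertz(published_le_quantiles())
  h5 <- gompertz_hazard(c(1, 5, 20), fit$rates[["5"]], fit$shape)
  h10 <- gompertz_hazard(c(1, 5, 20), fit$rates[["10"]], fit$shape)
  expect_equal(h10 / h5, rep(fit$rates[["10"]] / fit$rates[["5"]], 3))
  expect_equal(log(fit$rates[["10"]] / fit$rates[["5"]]),
               fit$beta[["10"]] - fit$beta[["5"]])
})
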