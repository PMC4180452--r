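test_that("Kaplan-Meier matches hand product-limit computations", {
  d <- tibble::tibble(group = "0", time_years = 1:4, event = TRUE)
  km <- km_curves(d)
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))

  d2 <- tibble::tibble(group = "0", time_years = c(1, 2, 3),
                       event = c(TRUE, FALSE, TRUE))
  km2 <- km_curves(d2)
  expect_equal(km2$surv[km2$n_event > 0], c(2 / 3, 0))

  all_cens <- tibble::tibble(group = "0", time_years = c(2, 5, 9),
                             event = FALSE)
  km3 <- km_curves(all_cens)
  expect_true(all(km3$surv == 1))
  q <- km_quantile(km3, 0.5)
  expect_true(q$not_reached[q$group == "0"])
})

test_that("Kaplan-Meier equals empirical survival when nothing is censored", {
  set.seed(81)
  d <- tibble::tibble(group = "3", time_years = round(rexp(120, 0.2), 2),
                      event = TRUE)
  km <- km_curves(d)
  emp <- vapply(km$time, function(t) mean(d$time_years > t), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
  # and matches the hand oracle with mixed censoring
  set.seed(82)
  d2 <- tibble::tibble(group = "3", time_years = round(rexp(60, 0.2), 1),
                       event = runif(60) < 0.6)
  if (!any(d2$event)) d2$event[1] <- TRUE
  km2 <- km_curves(d2)
  oracle <- km_by_hand(d2$time_years, d2$event)
  got <- km2[km2$n_event > 0, c("time", "surv")]
  expect_equal(got$time, oracle$time)
  expect_equal(got$surv, oracle$surv, tolerance = 1e-12)
})

test_that("concordance honours its tie conventions on worked pairs", {
  two <- tibble::tibble(group = c("2", "9"), time_years = c(8, 3),
                        event = TRUE)
  expect_equal(harrells_c(two)$concordance, 1)
  same <- tibble::tibble(group = rep("5", 6),
                         time_years = c(1, 2, 3, 4, 5, 6), event = TRUE)
  expect_equal(harrells_c(same)$concordance, 0.5)
  all_cens <- tibble::tibble(group = c("1", "8"), time_years = c(5, 5),
                             event = FALSE)
  expect_error(harrells_c(all_cens), "usable")
})

test_that("concordance equals exhaustive pair enumeration on small sets", {
  set.seed(91)
  for (rep in 1:15) {
    n <- sample(5:20, 1)
    d <- tibble::tibble(
      group = sample(c("0", "4", "9", "14+"), n, replace = TRUE),
      time_years = sample(1:8, n, replace = TRUE) / 2, # force time ties
      event = runif(n) < 0.65
    )
    score <- as.numeric(factor(d$group, levels = c("0", "4", "9", "14+")))
    oracle <- concordance_by_enumeration(d$time_years, d$event, score)
    if (is.na(oracle)) {
      expect_error(harrells_c(d), "usable")
    } else {
      expect_equal(harrells_c(d)$concordance, oracle, tolerance = 1e-12)
    }
  }
})

test_that("concordance agrees with the survival package on a large cohort", {
  spec <- hrs_cohort_spec("development")
  cohort <- sample_cohort(spec, n = 2500, seed = 17)
  mine <- harrells_c(cohort)$concordance
  ref <- survival::concordance(
    survival::Surv(time_years, event) ~ as.numeric(group),
    data = cohort, reverse = TRUE
  )$concordance
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("concordance is invariant to monotone score transforms and perfect
          separation gives 1", {
  spec <- hrs_cohort_spec("development")
  cohort <- sample_cohort(spec, n = 800, seed = 23)
  base <- harrells_c(cohort)$concordance
  pts <- as.numeric(cohort$group)
  expect_equal(harrells_c(cohort, score = exp(2 * pts))$concordance, base)
  expect_equal(harrells_c(cohort, score = -1 / (1 + pts))$concordance, base)

  # perfect separation with subject-unique scores and no censoring
  sep <- tibble::tibble(
    group = rep(c("1", "6", "12"), each = 5),
    time_years = c(21:25, 11:15, 1:5), event = TRUE
  )
  expect_equal(harrells_c(sep, score = 26 - sep$time_years)$concordance, 1)
  # with the 3 group-level scores, within-group pairs are score ties: each
  # contributes 1/2, so c drops below 1 by exactly the tie fraction
  cc <- harrells_c(sep)
  expect_equal(cc$concordance,
               (cc$concordant + 0.5 * cc$tied_score) / cc$n_pairs)
  expect_equal(cc$concordance, 1 - 0.5 * 30 / 105)
})

test_that("calibration test is exact on its chi-square arithmetic contracts", {
  fit <- reconstruct_gompertz(published_le_quantiles())
  one_group <- tibble::tibble(group = "5", time_years = pmin(rexp(50, 0.2), 10),
                              event = TRUE)
  one_group$event <- one_group$time_years < 10
  if (!any(one_group$event)) one_group$event[1] <- TRUE
  expect_error(hosmer_lemeshow(one_group, fit, horizon = 5), "df")
  spec <- hrs_cohort_spec("development")
  cohort <- sample_cohort(spec, n = 3000, seed = 29)
  expect_error(hosmer_lemeshow(cohort, fit, horizon = 50), "follow-up")
})

test_that("well-calibrated data passes and halved rates fail the calibration
          test", {
  model <- reconstruct_gompertz(published_le_quantiles())
  spec <- hrs_cohort_spec("validation")
  cohort <- sample_cohort(spec, seed = 37) # n = 8009 from the true model
  ok <- hosmer_lemeshow(cohort, model, horizon = 8, df_style = "external")
  expect_gt(ok$p_value, 0.01)
  expect_gte(ok$statistic, 0)
  miscal <- model
  miscal$rates <- model$rates / 2
  bad <- hosmer_lemeshow(cohort, miscal, horizon = 8, df_style = "external")
  expect_lt(bad$p_value, 0.001)
  # development df convention: G - 2
  dev <- hosmer_lemeshow(cohort, model, horizon = 8, df_style = "development")
  expect_identical(dev$df, ok$df - 2L)
})

test_that("small expected counts are merged with a warning", {
  model <- reconstruct_gompertz(published_le_quantiles())
  d <- dplyr::bind_rows(
    sample_cohort(hrs_cohort_spec("development"), n = 600, seed = 41),
    tibble::tibble(id = 0, group = "0", points = 0,
                   time_years = 10, event = FALSE)
  )
  d <- dplyr::filter(d, group %in% c("0", "10", "12", "14+"))
  expect_warning(
    res <- hosmer_lemeshow(d, model, horizon = 5, df_style = "external"),
    "merged"
  )
  expect_lt(res$n_groups, 4)
})

test_that("curve export pairs model and observed curves on a shared grid", {
  fit <- reconstruct_gompertz(published_le_quantiles())
  spec <- hrs_cohort_spec("development")
  cohort <- sample_cohort(spec, n = 2000, seed = 43)
  km <- km_curves(cohort)
  curves <- export_curves(fit, km, horizon = 10)
  at0 <- dplyr::filter(curves, curve == "predicted", time == 0)
  expect_equal(at0$surv, rep(1, nrow(at0)))
  expect_lte(max(curves$time), 10)
  # the top group's predicted survival at its published median is one half
  s34 <- model_surv <- dplyr::filter(curves, curve == "predicted",
                                     group == "14+")
  expect_equal(stats::approx(s34$time, s34$surv, xout = 3.4)$y, 0.5,
               tolerance = 0.005)
})

test_that("the bundled validation report reproduces its parts", {
  fit <- reconstruct_gompertz(published_le_quantiles())
  spec <- hrs_cohort_spec("validation")
  cohort <- sample_cohort(spec, n = 3000, seed = 47)
  rep <- validate_fit(cohort, fit, horizons = c(5, 8), df_style = "external",
                      label = "synthetic validation")
  expect_s3_class(rep, "validation_report")
  expect_equal(rep$harrells_c$concordance, harrells_c(cohort)$concordance)
  expect_identical(nrow(rep$hosmer_lemeshow), 2L)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
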