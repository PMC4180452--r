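# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms: cumulative hazards by quadrature, concordance by
# exhaustive pair enumeration, Kaplan-Meier by the hand product-limit recipe,
# and the shared-shape quantile-ratio equation solved by bisection.

# censored log-likelihood with the cumulative hazard integrated numerically
loglik_by_quadrature <- function(time, event, rate, shape) {
  haz <- function(u, lam) lam * exp(shape * u)
  cumhaz <- vapply(seq_along(time), function(i) {
    if (time[i] == 0) return(0)
    stats::integrate(haz, 0, time[i], lam = rate[i],
                     rel.tol = 1e-12, abs.tol = 1e-13)$value
  }, numeric(1))
  sum(log(rate[event]) + shape * time[event]) - sum(cumhaz)
}

# Harrell's c by brute-force enumeration of all subject pairs:
# usable = shorter time is a death (a death tied with a censoring counts,
# two tied deaths do not); concordant = higher score dies first;
# tied scores weight 1/2
concordance_by_enumeration <- function(time, event, score) {
  n <- length(time)
  conc <- tied <- usable <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) {
        if (event[i] && event[j]) next
        if (!event[i] && !event[j]) next
        first <- if (event[i]) i else j
      } else {
        first <- if (time[i] < time[j]) i else j
        if (!event[first]) next
      }
      second <- if (first == i) j else i
      usable <- usable + 1
      if (score[first] > score[second]) conc <- conc + 1
      else if (score[first] == score[second]) tied <- tied + 1
    }
  }
  if (usable == 0) return(NA_real_)
  (conc + 0.5 * tied) / usable
}

# hand product-limit estimator: S(t) = prod over event times <= t of
# (1 - d_k / n_k), with censorings at an event time still at risk for it
km_by_hand <- function(time, event) {
  ut <- sort(unique(time[event]))
  surv <- numeric(length(ut))
  s <- 1
  for (k in seq_along(ut)) {
    at_risk <- sum(time > ut[k]) + sum(time == ut[k])
    d <- sum(time == ut[k] & event)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = ut, surv = surv)
}

# shared shape from one (t25, t50) pair by bisection on the quantile-ratio
# equation (e^{g t50} - 1)/(e^{g t25} - 1) = ln(0.5)/ln(0.75)
shape_by_bisection <- function(t25, t50, lower = 1e-6, upper = 1) {
  target <- log(0.5) / log(0.75)
  f <- function(g) expm1(g * t50) / expm1(g * t25) - target
  stopifnot(f(lower) * f(upper) < 0)
  for (k in 1:200) {
    mid <- (lower + upper) / 2
    if (f(lower) * f(mid) <= 0) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}

# a tiny deterministic cohort exercising events, censoring and several groups
toy_cohort <- function() {
  tibble::tibble(
    group = c("0", "0", "2", "2", "2", "5", "5", "10", "10", "14+"),
    time_years = c(9.1, 10, 4.2, 7.5, 10, 2.3, 6.6, 1.2, 3.9, 0.7),
    event = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
}

# profile with every item switched off, at the youngest age band
blank_profile <- function(n = 1) {
  out <- tibble::tibble(age_years = rep(55, n))
  for (item in lee_item_points()$item) out[[item]] <- FALSE
  out
}
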