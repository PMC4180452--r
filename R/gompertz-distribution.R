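#' Gompertz hazard, survival, quantile and random generation
#'
#' The Gompertz hazard is \eqn{h(t) = \lambda e^{\gamma t}}: a baseline rate
#' \eqn{\lambda} (deaths per person-year at \eqn{t = 0}) growing exponentially
#' with shape \eqn{\gamma} (1/years), so that the hazard doubles every
#' \eqn{\ln 2 / \gamma} years. The cumulative hazard is
#' \eqn{H(t) = (\lambda/\gamma)(e^{\gamma t} - 1)} and survival
#' \eqn{S(t) = e^{-H(t)}}. All functions take `shape = 0` (and values near 0)
#' through a series branch, recovering the exponential distribution exactly,
#' and are vectorised over all arguments.
#'
#' `gompertz_quantile()` inverts survival at mortality fraction `p`:
#' \eqn{t_p = \gamma^{-1}\ln(1 - (\gamma/\lambda)\ln(1 - p))}. For negative
#' shape the hazard decays and total mortality plateaus at
#' \eqn{1 - \exp(\lambda/\gamma)}; requesting a deeper quantile is an error
#' (`"plateau"` condition).
#'
#' @param t Time in years, non-negative.
#' @param p Mortality fraction in (0, 1) (so `p = 0.5` gives median survival).
#' @param n Number of random survival times to draw.
#' @param rate Baseline hazard \eqn{\lambda > 0}, per year.
#' @param shape Gompertz shape \eqn{\gamma}, per year. May be zero or negative.
#' @return `gompertz_hazard()`, `gompertz_cumhaz()`, `gompertz_survival()` and
#'   `gompertz_quantile()` return numeric vectors; `rgompertz()` returns `n`
#'   survival times in years.
#' @examples
#' gompertz_hazard(0, rate = 0.01, shape = 0.1)   # equals the rate at t = 0
#' gompertz_survival(10, rate = 0.1, shape = 0)   # exponential: exp(-1)
#' gompertz_quantile(0.5, rate = 0.0015, shape = 0.112)  # median, years
#' @name gompertz
NULL

# expm1(x)/x with a series branch so cumulative hazards do not cancel
# catastrophically as shape*t -> 0
expm1_over_x <- function(x) {
  out <- ifelse(abs(x) < 1e-5, 1 + x / 2 + x^2 / 6, expm1(x) / x)
  out[x == 0] <- 1
  out
}

check_rate <- function(rate) {
  if (any(!is.finite(rate)) || any(rate <= 0)) {
    stop("`rate` must be a positive finite hazard (deaths per person-year).",
         call. = FALSE)
  }
  invisible(rate)
}

check_time <- function(t) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be a non-negative time in years.", call. = FALSE)
  }
  invisible(t)
}

#' @rdname gompertz
#' @export
gompertz_hazard <- function(t, rate, shape) {
  check_time(t)
  check_rate(rate)
  rate * exp(shape * t)
}

#' @rdname gompertz
#' @export
gompertz_cumhaz <- function(t, rate, shape) {
  check_time(t)
  check_rate(rate)
  rate * t * expm1_over_x(shape * t)
}

#' @rdname gompertz
#' @export
gompertz_survival <- function(t, rate, shape) {
  exp(-gompertz_cumhaz(t, rate, shape))
}

#' @rdname gompertz
#' @export
gompertz_quantile <- function(p, rate, shape) {
  check_rate(rate)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must be a mortality fraction strictly inside (0, 1).",
         call. = FALSE)
  }
  y <- -log1p(-p) # target cumulative hazard
  n <- max(length(p), length(rate), length(shape))
  p <- rep_len(p, n); rate <- rep_len(rate, n); shape <- rep_len(shape, n)
  y <- rep_len(y, n)
  out <- numeric(n)
  tiny <- abs(shape) * y / rate < 1e-9
  out[tiny] <- y[tiny] / rate[tiny]
  if (any(!tiny)) {
    arg <- shape[!tiny] * y[!tiny] / rate[!tiny]
    if (any(arg <= -1)) {
      stop("plateau: mortality fraction `p` is never reached when the hazard ",
           "decays (shape < 0); at most 1 - exp(rate/shape) of the group dies.",
           call. = FALSE)
    }
    out[!tiny] <- log1p(arg) / shape[!tiny]
  }
  out
}

#' @rdname gompertz
#' @export
rgompertz <- function(n, rate, shape) {
  gompertz_quantile(stats::runif(n), rate, shape)
}
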