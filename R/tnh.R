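#' The zero-point-mass + zero-truncated normal ("TNH") response distribution
#'
#' Density, distribution function, quantile function and random generation for
#' the daily adherence response: with probability `nu` the day is a
#' non-attempt (exactly zero hours); otherwise the time on therapy follows a
#' normal distribution with mean `mu` and standard deviation `sigma` of the
#' underlying (non-truncated) normal, left-truncated at zero.
#'
#' The truncation normalizer `1 - Phi(-mu/sigma) = Phi(mu/sigma)` is always
#' evaluated in log space (`pnorm(..., log.p = TRUE)`), so densities remain
#' finite and accurate when `mu/sigma` is large in either direction.
#'
#' @param x,q vector of quantiles (hours, `>= 0` for `dtnh`).
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param mu mean of the underlying normal (hours).
#' @param sigma standard deviation of the underlying normal (hours, `> 0`).
#' @param nu probability of a non-attempt (zero day), strictly inside (0, 1).
#' @param log,log.p logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#' @return `dtnh` a density vector, `ptnh`/`qtnh` probability/quantile
#'   vectors, `rtnh` a vector of hours in which non-attempts are literal `0`.
#' @examples
#' dtnh(0, mu = 5, sigma = 1, nu = 0.3)        # the point mass: 0.3
#' ptnh(1, mu = 0, sigma = 1, nu = 0.2)        # 0.2 + 0.8 * 0.68269
#' mean(rtnh(1e4, mu = 7, sigma = 1.5, nu = 0.113) == 0)
#' @name tnh
NULL

check_tnh_params <- function(mu, sigma, nu) {
  if (any(!is.finite(mu))) stop("`mu` must be finite", call. = FALSE)
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("`sigma` must be a positive, finite number of hours", call. = FALSE)
  }
  if (any(!is.finite(nu)) || any(nu <= 0) || any(nu >= 1)) {
    stop("`nu` must lie strictly inside (0, 1); boundary values are not valid hurdle probabilities",
         call. = FALSE)
  }
  invisible(TRUE)
}

# log Phi(mu/sigma), the log truncation normalizer
log_trunc_norm <- function(mu, sigma) pnorm(mu / sigma, log.p = TRUE)

#' @rdname tnh
#' @export
dtnh <- function(x, mu, sigma, nu, log = FALSE) {
  check_tnh_params(mu, sigma, nu)
  if (any(x < 0)) stop("negative hours are outside the support of the adherence response", call. = FALSE)
  n <- max(length(x), length(mu), length(sigma), length(nu))
  x <- rep_len(x, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  out <- numeric(n)
  zero <- x == 0
  out[zero] <- base::log(nu[zero])
  if (any(!zero)) {
    i <- !zero
    out[i] <- log1p(-nu[i]) +
      dnorm((x[i] - mu[i]) / sigma[i], log = TRUE) - base::log(sigma[i]) -
      log_trunc_norm(mu[i], sigma[i])
  }
  if (log) out else exp(out)
}

#' @rdname tnh
#' @export
ptnh <- function(q, mu, sigma, nu, log.p = FALSE) {
  check_tnh_params(mu, sigma, nu)
  n <- max(length(q), length(mu), length(sigma), length(nu))
  q <- rep_len(q, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  ft <- ptrunc_pos(q, mu, sigma)
  out <- ifelse(q < 0, 0, nu + (1 - nu) * ft)
  if (log.p) base::log(out) else out
}

# CDF of the positive (zero-truncated) part; 0 for q <= 0
ptrunc_pos <- function(q, mu, sigma) {
  lz <- log_trunc_norm(mu, sigma)
  # 1 - F = Phi((mu - q)/sigma) / Phi(mu/sigma), stable via log upper tail
  upper <- exp(pnorm((mu - q) / sigma, log.p = TRUE) - lz)
  out <- pmin(pmax(1 - upper, 0), 1)
  out[q <= 0] <- 0
  out
}

#' @rdname tnh
#' @export
qtnh <- function(p, mu, sigma, nu) {
  check_tnh_params(mu, sigma, nu)
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  n <- max(length(p), length(mu), length(sigma), length(nu))
  p <- rep_len(p, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  out <- numeric(n)
  pos <- p > nu
  if (any(pos)) {
    u <- (p[pos] - nu[pos]) / (1 - nu[pos])
    out[pos] <- qtrunc_pos(u, mu[pos], sigma[pos])
  }
  out
}

# quantile of the zero-truncated normal, stable for mu/sigma << 0:
# 1 - F(z) = (1 - u) * Phi(mu/sigma) on the standard-normal upper tail
qtrunc_pos <- function(u, mu, sigma) {
  lz <- log_trunc_norm(mu, sigma)
  z <- qnorm(log1p(-u) + lz, lower.tail = FALSE, log.p = TRUE)
  mu + sigma * z
}

#' @rdname tnh
#' @export
rtnh <- function(n, mu, sigma, nu) {
  check_tnh_params(mu, sigma, nu)
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  attempt <- runif(n) >= nu
  out <- numeric(n)
  if (any(attempt)) {
    out[attempt] <- qtrunc_pos(runif(sum(attempt)), mu[attempt], sigma[attempt])
  }
  out
}

#' Conditional moments of the zero-truncated normal
#'
#' First three moments of `X | X > 0` for a normal `X` with mean `mu` and
#' standard deviation `sigma`, computed through the inverse Mills ratio
#' `lambda = phi(mu/sigma) / Phi(mu/sigma)` evaluated in log space.
#'
#' @inheritParams tnh
#' @return a tibble with columns `mean`, `second_moment`, `third_moment`
#'   (hours, hours^2, hours^3), one row per parameter combination.
#' @examples
#' truncated_moments(0, 1)$mean   # half-normal: sqrt(2/pi)
#' @export
truncated_moments <- function(mu, sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("`sigma` must be a positive, finite number of hours", call. = FALSE)
  }
  n <- max(length(mu), length(sigma))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  a <- mu / sigma
  # inverse Mills ratio at -a: phi(a)/Phi(a), log-space for large |a|
  lambda <- exp(dnorm(a, log = TRUE) - pnorm(a, log.p = TRUE))
  delta <- -a * lambda + 1 # E[((X-mu)/sigma)^2 | X>0] term
  m1 <- mu + sigma * lambda
  m2 <- mu^2 + 2 * sigma * mu * lambda + sigma^2 * delta
  # third moment from the standard truncated-normal recursion
  # E[Z^3 | Z > -a] = lambda (2 + a^2); collected terms in mu cancel
  m3 <- mu^3 + 3 * mu * sigma^2 + (2 * sigma^3 + mu^2 * sigma) * lambda
  tibble::tibble(mean = m1, second_moment = m2, third_moment = m3)
}

#' Randomized quantile residuals for the hurdle response
#'
#' Maps each observation to a standard-normal quantile through the mixed
#' discrete-continuous CDF: exact zeros are randomized uniformly within the
#' point mass (`qnorm(u * nu)`), positive hours use the continuous CDF
#' (`qnorm(nu + (1 - nu) * F_trunc(y))`). Under the true model the residuals
#' are standard normal.
#'
#' @param y observed hours (`>= 0`).
#' @inheritParams tnh
#' @param u uniform(0, 1) randomization draws, one per observation; defaults
#'   to fresh draws. Values on the closed boundary are rejected.
#' @return numeric vector of residuals on the standard-normal scale.
#' @export
quantile_residual <- function(y, mu, sigma, nu, u = runif(length(y))) {
  check_tnh_params(mu, sigma, nu)
  if (any(y < 0)) stop("negative hours are outside the support of the adherence response", call. = FALSE)
  n <- length(y)
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  u <- rep_len(u, n)
  if (any(u <= 0 | u >= 1)) stop("`u` must lie strictly inside (0, 1)", call. = FALSE)
  out <- numeric(n)
  zero <- y == 0
  out[zero] <- qnorm(base::log(u[zero]) + base::log(nu[zero]), log.p = TRUE)
  if (any(!zero)) {
    i <- !zero
    out[i] <- qnorm(nu[i] + (1 - nu[i]) * ptrunc_pos(y[i], mu[i], sigma[i]))
  }
  out
}
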