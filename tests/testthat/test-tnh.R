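test_that("density puts the stated mass on the hurdle and the half-normal case", {
  expect_equal(dtnh(0, mu = 5, sigma = 1, nu = 0.3, log = TRUE), log(0.3))
  # truncation at the mean doubles the density of the positive part
  expect_equal(dtnh(1, mu = 0, sigma = 1, nu = 0.5, log = TRUE),
               log(0.5) + log(2 * dnorm(1)))
})

test_that("density normalizes: nu + integral of the positive part is 1", {
  grid <- expand.grid(ratio = c(-3, 0, 4), sigma = c(0.7, 1.5, 2.1),
                      nu = c(0.05, 0.113, 0.9))
  for (i in seq_len(nrow(grid))) {
    mu <- grid$ratio[i] * grid$sigma[i]
    mass <- integrate(function(y) dtnh(y, mu, grid$sigma[i], grid$nu[i]),
                      0, Inf, rel.tol = 1e-12)$value
    expect_lt(abs(grid$nu[i] + mass - 1), 1e-8)
  }
  mass <- integrate(function(y) dtnh(y, 6.7, 2.1, 0.113), 0, Inf,
                    rel.tol = 1e-12)$value
  expect_lt(abs(0.113 + mass - 1), 1e-8)
})

test_that("mixed CDF has the point mass, monotonicity and the right limits", {
  expect_equal(ptnh(-1, 6, 2, 0.113), 0)
  expect_equal(ptnh(0, 6, 2, 0.113), 0.113)
  expect_equal(ptnh(1e6, 6, 2, 0.113), 1)
  # hand value from standard-normal table arithmetic
  expect_equal(ptnh(1, 0, 1, 0.2),
               0.2 + 0.8 * (pnorm(1) - pnorm(0)) / (1 - pnorm(0)),
               tolerance = 1e-12)
  q <- seq(0, 14, by = 0.25)
  expect_true(all(diff(ptnh(q, 6.7, 2.1, 0.113)) >= 0))
})

test_that("CDF derivative matches the density on the positive part", {
  y <- c(0.5, 2, 5, 6.7, 9, 13)
  h <- 1e-5
  num <- (ptnh(y + h, 6.7, 2.1, 0.113) - ptnh(y - h, 6.7, 2.1, 0.113)) / (2 * h)
  expect_equal(num, dtnh(y, 6.7, 2.1, 0.113), tolerance = 1e-6)
})

test_that("truncated moments match quadrature and their limits", {
  m <- truncated_moments(0, 1)
  expect_equal(m$mean, sqrt(2 / pi), tolerance = 1e-12)
  expect_equal(truncated_moments(10, 0.5)$mean, 10, tolerance = 1e-10)
  # moments reduce to the untruncated ones far from the boundary
  m8 <- truncated_moments(8, 1)
  expect_equal(m8$mean, 8, tolerance = 1e-8)
  expect_equal(m8$second_moment, 65, tolerance = 1e-8)
  for (mu in c(-3.4, 0, 7.1)) {
    for (sigma in c(0.6, 1.7, 2.8)) {
      dens <- function(y, k) y^k * dnorm(y, mu, sigma) / pnorm(mu / sigma)
      ref <- vapply(1:3, function(k) {
        integrate(dens, 0, Inf, k = k, rel.tol = 1e-12)$value
      }, 0)
      got <- unlist(truncated_moments(mu, sigma))
      expect_equal(got, ref, tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("sampling agrees with the hurdle rate and the positive-part law", {
  set.seed(401)
  n <- 1e5
  y <- rtnh(n, mu = 7, sigma = 1.5, nu = 0.113)
  zf <- mean(y == 0)
  expect_lt(abs(zf - 0.113), 3 * sqrt(0.113 * 0.887 / n))
  pos <- y[y > 0]
  m <- truncated_moments(7, 1.5)
  sd_pos <- sqrt(m$second_moment - m$mean^2)
  expect_lt(abs(mean(pos) - m$mean), 3 * sd_pos / sqrt(length(pos)))
  # distributional agreement of the positive part (seeded KS)
  ks <- suppressWarnings(ks.test(pos, function(q) {
    (ptnh(q, 7, 1.5, 0.113) - 0.113) / (1 - 0.113)
  }))
  expect_gt(ks$p.value, 0.01)
  # extreme hurdle probability still yields the expected trickle of attempts
  y2 <- rtnh(n, 7, 1.5, 0.999)
  expect_lt(abs(mean(y2 > 0) - 0.001), 3 * sqrt(0.001 * 0.999 / n))
})

test_that("sampling is stable when the truncation removes most of the mass", {
  set.seed(402)
  y <- rtnh(2e4, mu = -8, sigma = 1, nu = 0.5)
  pos <- y[y > 0]
  expect_true(all(pos > 0))
  m <- truncated_moments(-8, 1)
  expect_equal(mean(pos), m$mean, tolerance = 0.05)
})

test_that("quantile residuals are standard normal under the true model", {
  expect_equal(quantile_residual(0, 5, 1, 0.2, u = 0.5), qnorm(0.1),
               tolerance = 1e-12)
  # positive observation at the conditional median
  med <- qtnh(0.113 + (1 - 0.113) * 0.5, 6.7, 2.1, 0.113)
  expect_equal(quantile_residual(med, 6.7, 2.1, 0.113, u = 0.5),
               qnorm(0.113 + (1 - 0.113) * 0.5), tolerance = 1e-9)
  set.seed(403)
  y <- rtnh(1e4, 6.7, 2.1, 0.113)
  r <- quantile_residual(y, 6.7, 2.1, 0.113)
  ks <- ks.test(r, pnorm)
  # KS distance below the 1% critical value
  expect_lt(unname(ks$statistic), 1.63 / sqrt(length(r)))
})

test_that("invalid parameters and domains are rejected", {
  expect_error(dtnh(1, 5, 0, 0.3), "sigma")
  expect_error(dtnh(1, 5, 1, 0), "nu")
  expect_error(dtnh(1, 5, 1, 1), "nu")
  expect_error(dtnh(-1, 5, 1, 0.3), "negative")
  expect_error(quantile_residual(1, 5, 1, 0.3, u = 1), "u")
  expect_error(truncated_moments(5, -1), "sigma")
})
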