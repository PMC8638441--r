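two_identical_class_model <- function(pi = c(0.3, 0.7)) {
  cc <- class_coefficients(c(6.5, 0, 0), c(0.3, 0, 0), c(-2, 0, 0))
  hurdle_mixture(list(cc, cc), pi, sigma_gamma = 1.0)
}

test_that("responsibilities reduce to the prior when classes are identical", {
  sim <- simulate_cohort(three_class_scenario(15), seed = 31)
  m <- two_identical_class_model()
  w <- e_step(sim$data, m)
  expect_equal(unname(w), matrix(rep(c(0.7, 0.3), each = 15), 15, 2),
               tolerance = 1e-12)
  # G = 1: all weights exactly 1
  cc <- m$classes[[1]]
  m1 <- hurdle_mixture(list(cc), 1, sigma_gamma = 1.0)
  expect_equal(unname(e_step(sim$data, m1)), matrix(1, 15, 1))
})

test_that("a one-day toy posterior matches Bayes' rule on log-densities", {
  c1 <- class_coefficients(c(7, 0, 0), c(0, 0, 0), c(-2, 0, 0))
  c2 <- class_coefficients(c(5, 0, 0), c(0.3, 0, 0), c(-1, 0, 0))
  m <- hurdle_mixture(list(c1, c2), c(0.6, 0.4), sigma_gamma = 0, n_nodes = 1)
  d <- tibble::tibble(patient_id = "p1", day = 3, hours = 6.2)
  w <- e_step(d, m)
  p1 <- evaluate_predictors(m$classes[[1]], 3)
  p2 <- evaluate_predictors(m$classes[[2]], 3)
  l1 <- dtnh(6.2, p1$mu, p1$sigma, p1$nu)
  l2 <- dtnh(6.2, p2$mu, p2$sigma, p2$nu)
  post1 <- m$pi[1] * l1 / (m$pi[1] * l1 + m$pi[2] * l2)
  expect_equal(unname(w[1, 1]), post1, tolerance = 1e-12)
})

test_that("E-step rows sum to one and the M-step averages responsibilities", {
  sim <- simulate_cohort(three_class_scenario(100), seed = 33)
  m <- two_identical_class_model(c(0.25, 0.75))
  w <- e_step(sim$data, m)
  expect_lt(max(abs(rowSums(w) - 1)), 1e-10)
  expect_equal(unname(colMeans(w)), c(0.75, 0.25), tolerance = 1e-12)
  m2 <- m_step(sim$data, w, m)
  expect_equal(m2$pi, colMeans(w), tolerance = 1e-12)
  # all-ones single column
  m1 <- hurdle_mixture(m$classes[1], 1, 1.0)
  w1 <- matrix(1, 100, 1)
  expect_equal(m_step(sim$data, w1, m1)$pi, 1)
})

test_that("one EM cycle does not decrease the marginal log-likelihood", {
  sim <- simulate_cohort(three_class_scenario(80), seed = 35)
  idx <- hurdletraj:::cohort_index(sim$data)
  m <- two_identical_class_model()
  gh <- hurdletraj:::gh_rule(m$ri$n_nodes)
  set.seed(1)
  w0 <- matrix(rexp(80 * 2), 80, 2)
  w0 <- w0 / rowSums(w0)
  ll_of <- function(mod) {
    hurdletraj:::posteriors_from_loglik(
      hurdletraj:::loglik_matrix(idx, mod, gh), mod$pi)$loglik
  }
  m1 <- m_step(sim$data, w0, m)
  w1 <- e_step(sim$data, m1)
  m2 <- m_step(sim$data, w1, m1)
  expect_gte(ll_of(m2), ll_of(m1) - 1e-6 * abs(ll_of(m1)))
})

test_that("relative entropy has its exact endpoints and hand value", {
  wu <- matrix(1 / 3, 10, 3)
  expect_equal(relative_entropy(wu), 0)
  wh <- diag(3)[rep(1:3, 4), ]
  expect_equal(relative_entropy(wh), 1)
  w <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  hand <- 1 - ((-0.9 * log(0.9) - 0.1 * log(0.1)) + log(2)) / (2 * log(2))
  expect_equal(relative_entropy(w), hand, tolerance = 1e-10)
  expect_equal(hand, 0.2655, tolerance = 1e-3)
  expect_error(relative_entropy(matrix(1, 5, 1)), "G = 1")
})

test_that("information criterion applies the penalty to the parameter count", {
  fake <- structure(list(loglik = 0, model = list(G = 1)),
                    class = "hurdletraj_fit")
  expect_equal(information_criterion(fake, penalty = 2), 2 * 10)
  fake3 <- structure(list(loglik = -100, model = list(G = 3)),
                     class = "hurdletraj_fit")
  m <- 9 * 3 + 2 + 1
  expect_equal(information_criterion(fake3), 2 * m + 200)
  expect_equal(information_criterion(fake3, penalty = log(500)),
               log(500) * m + 200)
  expect_equal(AIC(fake3), information_criterion(fake3))
})

test_that("label permutation leaves the model and posteriors invariant", {
  cl <- three_class_scenario()$classes
  pi <- c(0.5, 0.3, 0.2)
  m1 <- hurdle_mixture(cl, pi, 1.5)
  m2 <- hurdle_mixture(cl[c(3, 1, 2)], pi[c(3, 1, 2)], 1.5)
  expect_equal(m1$pi, m2$pi)
  expect_equal(m1$classes, m2$classes)
  sim <- simulate_cohort(three_class_scenario(25), seed = 37)
  expect_equal(e_step(sim$data, m1), e_step(sim$data, m2), tolerance = 1e-12)
})

test_that("hard-assignment complete-data log-likelihood is an EM lower bound", {
  sim <- simulate_cohort(three_class_scenario(40), seed = 39)
  idx <- hurdletraj:::cohort_index(sim$data)
  m <- hurdle_mixture(three_class_scenario()$classes, c(0.5, 0.3, 0.2), 1.5)
  gh <- hurdletraj:::gh_rule(21)
  llmat <- hurdletraj:::loglik_matrix(idx, m, gh)
  a <- sweep(llmat, 2, log(m$pi), "+")
  marg <- hurdletraj:::row_logsumexp(a)
  w <- exp(a - marg)
  # complete-data log-lik with modal hard assignment never exceeds the marginal
  hard <- a[cbind(seq_len(nrow(a)), max.col(a, ties.method = "first"))]
  expect_true(all(hard <= marg + 1e-12))
  # and the EM decomposition is exact: E_w[log pi + ll] + entropy = marginal
  ent <- rowSums(ifelse(w > 0, -w * log(w), 0))
  expect_equal(rowSums(w * a) + ent, marg, tolerance = 1e-8)
})

test_that("a serialized model round-trips losslessly", {
  fitlike <- hurdle_mixture(three_class_scenario()$classes, c(0.5, 0.3, 0.2),
                            sigma_gamma = 1.4927361, n_nodes = 21)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  write_model(fitlike, path)
  back <- read_model(path)
  expect_equal(back$pi, fitlike$pi, tolerance = 0)
  expect_equal(back$classes, fitlike$classes, tolerance = 0)
  expect_equal(back$ri$sigma_gamma, fitlike$ri$sigma_gamma, tolerance = 0)
})

test_that("a small two-class mixture fit is monotone and sane", {
  cl <- list(
    class_coefficients(c(7.2, 0, 0), c(0, 0, 0), c(-3.5, 0, 0), label = "hi"),
    class_coefficients(c(4.6, -0.01, 0), c(log(1.6), 0, 0), c(-0.5, 0.02, 0),
                       label = "lo")
  )
  sc <- simulation_scenario(cl, c(0.6, 0.4), sigma_gamma = 1.2, n_patients = 120)
  sim <- simulate_cohort(sc, seed = 41)
  fit <- fit_mixture(sim$data, G = 2, control = em_control(n_restarts = 2), seed = 5)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_path) > -1e-6 * abs(fit$loglik)))
  expect_lt(max(abs(rowSums(fit$posteriors) - 1)), 1e-10)
  expect_equal(fit$model$pi[1], 0.6, tolerance = 0.1)
  expect_gt(relative_entropy(fit$posteriors), 0.8)
  # deviance consistency
  expect_equal(fit$deviance, -2 * fit$loglik)
})
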