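test_that("modal assignment takes the row argmax with a deterministic tie rule", {
  w <- rbind(c(0.2, 0.8), c(0.5, 0.5), c(0.9, 0.1))
  rownames(w) <- c("a", "b", "c")
  a <- modal_assign(w)
  expect_equal(a$class, c(2, 1, 1))
  expect_equal(a$posterior_prob, c(0.8, 0.5, 0.9))
  expect_equal(a$patient_id, c("a", "b", "c"))
})

test_that("trajectory tables reproduce published cells and constants", {
  sc <- paper_scenario()
  m <- hurdle_mixture(sc$classes, sc$pi, sc$sigma_gamma)
  tab <- trajectory_table(m, days = c(1, 45, 90))
  B90 <- tab[tab$label == "B" & tab$day == 90, ]
  expect_equal(B90$mean_hours_r, 7.3)
  C45 <- tab[tab$label == "C" & tab$day == 45, ]
  expect_equal(C45$mean_hours_r, 7.0)
  cc <- class_coefficients(c(6, 0, 0), c(0.1, 0, 0), c(-2, 0, 0))
  m2 <- hurdle_mixture(list(cc), 1)
  tab2 <- trajectory_table(m2, days = c(1, 30, 60, 90))
  expect_equal(length(unique(tab2$mean_hours)), 1)
  expect_equal(length(unique(tab2$attempt_prob)), 1)
})

test_that("adherence summaries count attempted and compliant days", {
  d <- tibble::tibble(
    patient_id = rep(c("p1", "p2"), each = 90),
    day = rep(1:90, 2),
    hours = c(rep(c(5, 3), 45),        # p1: 45 days above 4 h
              rep(0, 90))              # p2: never attempts
  )
  assign <- tibble::tibble(patient_id = c("p1", "p2"), class = c(1, 1),
                           posterior_prob = c(1, 1))
  s <- adherence_summaries(d, assign, compliance_hours = 4)
  all_rows <- s[s$period == "all", ]
  expect_equal(all_rows$median[all_rows$metric == "pct_compliant"], 25) # (50 + 0)/2
  p1_only <- adherence_summaries(d[d$patient_id == "p1", ], assign[1, ])
  expect_equal(p1_only$median[p1_only$metric == "pct_compliant" &
                                p1_only$period == "all"], 50)
  # the all-zero patient contributes missing on-therapy statistics
  expect_equal(all_rows$n[all_rows$metric == "mean_hours_attempted"], 1)
})

test_that("summaries track the hurdle rate on simulated data", {
  cc <- class_coefficients(c(6, 0, 0), c(0, 0, 0), c(qlogis(0.1), 0, 0))
  sc <- simulation_scenario(list(cc), 1, sigma_gamma = 0, n_patients = 200)
  sim <- simulate_cohort(sc, seed = 81)
  assign <- tibble::tibble(patient_id = unique(sim$data$patient_id), class = 1)
  s <- adherence_summaries(sim$data, assign)
  med <- s$median[s$metric == "pct_attempted" & s$period == "all"]
  expect_lt(abs(med - 90), 2)
})

test_that("summaries are invariant to patient order", {
  sim <- simulate_cohort(three_class_scenario(30), seed = 83)
  assign <- tibble::tibble(patient_id = unique(sim$data$patient_id),
                           class = rep(1:3, 10))
  s1 <- adherence_summaries(sim$data, assign)
  shuffled <- sim$data[sample(nrow(sim$data)), ]
  s2 <- adherence_summaries(shuffled, assign)
  expect_equal(s1, s2)
})

test_that("the ANOVA F statistic equals the textbook formula", {
  set.seed(85)
  values <- c(rnorm(20, 10), rnorm(25, 11), rnorm(30, 9))
  cls <- rep(1:3, c(20, 25, 30))
  ids <- sprintf("p%03d", seq_along(values))
  assign <- tibble::tibble(patient_id = ids, class = cls)
  cov <- tibble::tibble(patient_id = ids, value = values)
  res <- compare_groups(cov, assign, test = "f_test")
  # independent between/within mean-square computation
  gm <- mean(values)
  ni <- tapply(values, cls, length)
  mi <- tapply(values, cls, mean)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((values - mi[as.character(cls)])^2)
  Fref <- (ssb / 2) / (ssw / (length(values) - 3))
  expect_equal(res$statistic, Fref, tolerance = 1e-10)
  expect_equal(res$df, c(2, length(values) - 3))
  kw <- compare_groups(cov, assign, test = "kruskal_wallis")
  expect_equal(kw$statistic,
               unname(kruskal.test(values, factor(cls))$statistic),
               tolerance = 1e-12)
})

test_that("null covariates do not produce spuriously tiny p-values", {
  set.seed(87)
  values <- rnorm(400)
  assign <- tibble::tibble(patient_id = sprintf("p%03d", 1:400),
                           class = rep(1:2, each = 200))
  cov <- tibble::tibble(patient_id = assign$patient_id, value = values)
  res <- compare_groups(cov, assign, test = "f_test")
  expect_gt(res$p_value, 0.001)
})

test_that("degenerate group structures are handled as specified", {
  assign <- tibble::tibble(patient_id = sprintf("p%d", 1:5),
                           class = c(1, 1, 2, 2, 3))
  cov <- tibble::tibble(patient_id = assign$patient_id, value = c(1, 2, 3, 4, 5))
  expect_warning(res <- compare_groups(cov, assign), "fewer than 2")
  expect_equal(nrow(res$descriptives), 2)
  const <- tibble::tibble(patient_id = assign$patient_id, value = rep(1, 5))
  expect_warning(rc <- compare_groups(const, assign), "fewer than 2")
  expect_true(is.na(rc$statistic))
  one <- tibble::tibble(patient_id = c("p1", "p2"), value = c(1, 2))
  a1 <- tibble::tibble(patient_id = c("p1", "p2"), class = c(1, 1))
  expect_error(compare_groups(one, a1), "two groups")
})

test_that("worm data is empty on empty input and calibrated under the truth", {
  m <- hurdle_mixture(three_class_scenario()$classes, c(0.5, 0.3, 0.2), 1.5)
  empty <- residual_diagnostics(
    tibble::tibble(patient_id = character(), day = integer(), hours = numeric()), m)
  expect_equal(nrow(empty), 0)
  sim <- simulate_cohort(three_class_scenario(60), seed = 91)
  worm <- residual_diagnostics(sim$data, m, seed = 1)
  expect_equal(nrow(worm), nrow(sim$data))
  # the 95% envelope excludes a well-specified dataset 5% of the time by
  # construction, so calibration is checked as a binomial bound on the
  # exceedance count across independent datasets
  env <- worm_envelope_model(m, n_patients = 60, n_sim = 99, seed = 2)
  exceed <- vapply(1:15, function(s) {
    simb <- simulate_cohort(three_class_scenario(60), seed = 200 + s)
    wb <- residual_diagnostics(simb$data, m, seed = s)
    max(abs(wb$detrended_deviation)) > env$max_abs_critical
  }, logical(1))
  expect_lte(sum(exceed), 3) # P(X > 3 | n = 15, p = 0.05) ~ 0.5%
})

test_that("a misspecified scale inflates the worm-plot tails", {
  sim <- simulate_cohort(three_class_scenario(60), seed = 91)
  cl <- three_class_scenario()$classes
  halved <- lapply(cl, function(cc) {
    class_coefficients(cc$beta_mu,
                       cc$beta_logsigma - c(log(2), 0, 0),
                       cc$beta_logitnu, label = cc$label)
  })
  m_bad <- hurdle_mixture(halved, c(0.5, 0.3, 0.2), 1.5)
  worm <- residual_diagnostics(sim$data, m_bad, seed = 1)
  env <- worm_envelope_model(m_bad, n_patients = 60, n_sim = 60, seed = 2)
  expect_gt(max(abs(worm$detrended_deviation)), env$max_abs_critical)
})
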