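#' Simulation scenario for a synthetic adherence cohort
#'
#' Bundles the generative structure of the cohort simulator: the latent
#' classes with their mixing proportions, the patient random-intercept SD on
#' the mean, the cohort size and follow-up length, and the measurement cap
#' above which device records are considered unreliable (draws beyond it are
#' resampled rather than produced).
#'
#' @param classes list of [class_coefficients()].
#' @param pi mixing proportions (sum to 1).
#' @param sigma_gamma random-intercept SD (hours).
#' @param n_patients cohort size.
#' @param n_days days of follow-up per patient (default 90).
#' @param max_hours upper bound on plausible daily usage (default 15 h).
#' @return an object of class `sim_scenario`.
#' @export
simulation_scenario <- function(classes, pi, sigma_gamma = 1.5,
                                n_patients = 500, n_days = 90,
                                max_hours = 15) {
  stopifnot(length(classes) == length(pi), n_days >= 1, n_patients >= 1)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-6) {
    stop("`pi` must be non-negative proportions summing to 1", call. = FALSE)
  }
  structure(
    list(classes = classes, pi = pi / sum(pi), sigma_gamma = sigma_gamma,
         n_patients = as.integer(n_patients), n_days = as.integer(n_days),
         max_hours = max_hours),
    class = "sim_scenario"
  )
}

#' The nine-class CPAP adherence scenario
#'
#' The fitted nine-group solution for first-90-day CPAP therapy, as a
#' generative preset: per-class quadratic coefficients for mean usage,
#' log day-to-day SD and logit non-attempt probability (converted from the
#' published scaled columns to the raw day scale), mixing proportions
#' `(.16, .12, .23, .13, .08, .08, .09, .06, .05)`, and a patient
#' random-intercept SD of 1.5 hours. Labels A-I follow the published group
#' names (variable users, consistent users, good users, stable decliners,
#' strugglers, improvers, variable decliners, dropouts, early dropouts).
#'
#' @param n_patients cohort size for simulation (default 10000, the size of
#'   the analyzed study sample).
#' @return a [simulation_scenario()].
#' @export
paper_scenario <- function(n_patients = 10000) {
  # label, pi, logit-nu (int, t, t^2), mu (int, t, t^2), log-sigma (int, t, t^2)
  rows <- list(
    list("A", .16, c(-4.2, .0032, .093e-3), c(7.1, -.015, .093e-3), c(.52, .10e-2, .0057e-4)),
    list("B", .12, c(-4.1, -.015, .18e-3), c(7.4, -.0021, .012e-3), c(-.11, -.31e-2, .36e-4)),
    list("C", .23, c(-4.1, -.025, .26e-3), c(7.1, -.0034, .023e-3), c(.29, -.36e-2, .39e-4)),
    list("D", .13, c(-2.6, .018, -.03e-3), c(6.3, -.014, .090e-3), c(.29, -.064e-2, .20e-4)),
    list("E", .08, c(-1.3, .042, -.46e-3), c(5.3, -.012, .17e-3), c(.65, -.15e-2, .12e-4)),
    list("F", .08, c(-2.0, -.015, -.014e-3), c(5.2, .035, -.19e-3), c(.79, -.88e-2, .57e-4)),
    list("G", .09, c(-2.8, .014, .029e-3), c(6.6, -.018, .096e-3), c(.84, -.011e-2, .13e-4)),
    list("H", .06, c(-2.3, .032, .15e-3), c(5.6, -.020, .053e-3), c(.68, -.49e-2, .69e-4)),
    list("I", .05, c(-1.1, .11, -.94e-3), c(5.0, -.044, .47e-3), c(.60, -.13e-2, .29e-4))
  )
  classes <- lapply(rows, function(r) {
    class_coefficients(beta_mu = r[[4]], beta_logsigma = r[[5]],
                       beta_logitnu = r[[3]], label = r[[1]])
  })
  pi <- vapply(rows, function(r) r[[2]], 0)
  simulation_scenario(classes, pi, sigma_gamma = 1.5,
                      n_patients = n_patients, n_days = 90, max_hours = 15)
}

#' Simulate an adherence cohort
#'
#' Per patient: a class is drawn from `pi` and an intercept
#' `gamma ~ N(0, sigma_gamma^2)`; per day: a Bernoulli attempt with
#' probability `1 - nu(t)`, then zero-truncated normal hours with mean
#' `mu(t) + gamma` and SD `sigma(t)`. Draws exceeding `max_hours` are
#' resampled, so simulated trajectories are complete. Ground-truth labels
#' and intercepts are returned separately, never inside the data table.
#'
#' @param scenario a [simulation_scenario()].
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return a list with `data` (tibble `patient_id`, `day`, `hours`) and
#'   `truth` (tibble `patient_id`, `class`, `label`, `gamma`).
#' @export
simulate_cohort <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(seed)
  n <- scenario$n_patients
  G <- length(scenario$classes)
  days <- seq_len(scenario$n_days)
  cls <- sample.int(G, n, replace = TRUE, prob = scenario$pi)
  gamma <- rnorm(n, 0, scenario$sigma_gamma)

  # per-class day grid of distribution parameters
  grid <- lapply(scenario$classes, evaluate_predictors, t = days)

  ids <- sprintf("P%05d", seq_len(n))
  pid <- rep(seq_len(n), each = scenario$n_days)
  day <- rep(days, n)
  g_obs <- cls[pid]
  mu <- numeric(length(pid)); sig <- numeric(length(pid)); nu <- numeric(length(pid))
  for (g in seq_len(G)) {
    sel <- g_obs == g
    mu[sel] <- grid[[g]]$mu[day[sel]]
    sig[sel] <- grid[[g]]$sigma[day[sel]]
    nu[sel] <- grid[[g]]$nu[day[sel]]
  }
  mu <- mu + gamma[pid]
  if (any((mu / sig) < -8)) {
    warning("some simulated days have mu/sigma < -8; hours will be numerically near zero")
  }
  attempt <- rbinom(length(pid), 1, 1 - nu) == 1
  hours <- numeric(length(pid))
  todo <- which(attempt)
  while (length(todo)) {
    hours[todo] <- qtrunc_pos(runif(length(todo)), mu[todo], sig[todo])
    todo <- todo[hours[todo] > scenario$max_hours]
  }
  labels <- vapply(seq_len(G), function(g) {
    l <- scenario$classes[[g]]$label
    if (is.null(l)) as.character(g) else l
  }, "")
  list(
    data = tibble::tibble(patient_id = ids[pid], day = day, hours = hours),
    truth = tibble::tibble(patient_id = ids, class = cls,
                           label = labels[cls], gamma = gamma)
  )
}

#' Write / read a simulation scenario as YAML
#'
#' @param scenario a [simulation_scenario()].
#' @param path file path.
#' @return `write_scenario` returns `path` invisibly; `read_scenario` the
#'   reconstructed scenario.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "sim_scenario"))
  doc <- list(
    sigma_gamma = scenario$sigma_gamma, n_patients = scenario$n_patients,
    n_days = scenario$n_days, max_hours = scenario$max_hours,
    pi = scenario$pi,
    classes = lapply(scenario$classes, function(cc) {
      list(label = cc$label, beta_mu = cc$beta_mu,
           beta_logsigma = cc$beta_logsigma, beta_logitnu = cc$beta_logitnu)
    })
  )
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  classes <- lapply(doc$classes, function(cc) {
    class_coefficients(cc$beta_mu, cc$beta_logsigma, cc$beta_logitnu,
                       label = cc$label)
  })
  simulation_scenario(classes, unlist(doc$pi), doc$sigma_gamma,
                      doc$n_patients, doc$n_days, doc$max_hours)
}
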