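#' Modal class assignment
#'
#' Assigns each patient to the class with the highest posterior
#' responsibility; exact ties go to the lowest class index.
#'
#' @param w responsibility matrix (rows sum to 1), rownames = patient ids.
#' @return a tibble with columns `patient_id`, `class`, `posterior_prob`.
#' @export
modal_assign <- function(w) {
  stopifnot(is.matrix(w))
  cls <- max.col(w, ties.method = "first")
  tibble::tibble(
    patient_id = if (is.null(rownames(w))) as.character(seq_len(nrow(w))) else rownames(w),
    class = cls,
    posterior_prob = w[cbind(seq_len(nrow(w)), cls)]
  )
}

#' Group trajectories at selected days
#'
#' Evaluates the three linked predictors of every class at the requested
#' days. Unrounded values are returned together with a rounded view in the
#' published format (whole-percent attempt probability, 0.1-hour usage).
#'
#' @param model a [hurdle_mixture()] or `hurdletraj_fit`.
#' @param days days to evaluate (default `c(1, 45, 90)`).
#' @return a tibble with columns `class`, `label`, `pi`, `day`,
#'   `attempt_prob`, `mean_hours`, `sd_hours` and rounded counterparts
#'   `attempt_pct`, `mean_hours_r`, `sd_hours_r`.
#' @export
trajectory_table <- function(model, days = c(1, 45, 90)) {
  if (inherits(model, "hurdletraj_fit")) model <- model$model
  stopifnot(inherits(model, "hurdle_mixture"))
  purrr::imap_dfr(model$classes, function(cc, g) {
    pred <- evaluate_predictors(cc, days)
    tibble::tibble(
      class = g,
      label = if (is.null(cc$label)) as.character(g) else cc$label,
      pi = model$pi[g],
      day = pred$day,
      attempt_prob = 1 - pred$nu,
      mean_hours = pred$mu,
      sd_hours = pred$sigma,
      attempt_pct = round(100 * (1 - pred$nu)),
      mean_hours_r = round(pred$mu, 1),
      sd_hours_r = round(pred$sigma, 1)
    )
  })
}

per_patient_summary <- function(data, compliance_hours) {
  dplyr::summarise(
    dplyr::group_by(data, .data$patient_id),
    n_days = dplyr::n(),
    pct_attempted = 100 * mean(.data$hours > 0),
    pct_compliant = 100 * mean(.data$hours > compliance_hours),
    mean_hours_attempted = ifelse(any(.data$hours > 0),
                                  mean(.data$hours[.data$hours > 0]), NA_real_),
    sd_hours_attempted = ifelse(sum(.data$hours > 0) > 1,
                                sd(.data$hours[.data$hours > 0]), NA_real_),
    .groups = "drop"
  )
}

#' Per-group adherence summaries
#'
#' For each assigned group and for two periods (week 1 = days 1-7, and all
#' days): the distribution across patients of % attempted days (hours > 0),
#' % compliant days (hours above the compliance threshold), mean hours on
#' attempted days, and the within-patient SD of hours on attempted days.
#' Patients with no attempted days report missing on-therapy statistics.
#'
#' @param data a cohort tibble.
#' @param assign output of [modal_assign()].
#' @param compliance_hours daily compliance threshold (default 4 h, the US
#'   reimbursement convention).
#' @return a tibble with columns `class`, `period`, `metric`, `n`, `median`,
#'   `q25`, `q75`, `mean`, `sd`.
#' @export
adherence_summaries <- function(data, assign, compliance_hours = 4) {
  joined <- dplyr::inner_join(data, assign, by = "patient_id")
  missing_cls <- setdiff(assign$class, joined$class)
  if (length(missing_cls)) {
    warning("group(s) without any observations omitted: ",
            paste(missing_cls, collapse = ", "))
  }
  periods <- list(week1 = dplyr::filter(joined, .data$day <= 7), all = joined)
  purrr::imap_dfr(periods, function(d, pname) {
    pp <- per_patient_summary(d, compliance_hours)
    pp <- dplyr::inner_join(pp, assign[, c("patient_id", "class")], by = "patient_id")
    long <- tidyr::pivot_longer(
      pp, c("pct_attempted", "pct_compliant", "mean_hours_attempted", "sd_hours_attempted"),
      names_to = "metric", values_to = "value"
    )
    dplyr::summarise(
      dplyr::group_by(long, .data$class, .data$metric),
      period = pname,
      n = sum(!is.na(.data$value)),
      median = median(.data$value, na.rm = TRUE),
      q25 = quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
      q75 = quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
  })
}

#' Compare an external covariate across assigned groups
#'
#' One-way ANOVA F-test for means, or Kruskal-Wallis for medians of skewed
#' covariates, on a per-patient covariate after modal assignment
#' (the classical three-step approach, no misclassification correction).
#' Groups with fewer than 2 non-missing observations are excluded with a
#' warning; raw p-values are reported without multiplicity correction.
#'
#' @param covariate a data frame with `patient_id` and one numeric column,
#'   or a vector named by patient id.
#' @param assign output of [modal_assign()].
#' @param test `"f_test"` or `"kruskal_wallis"`.
#' @return a list: `statistic`, `p_value`, `df`, `method`, and
#'   `descriptives` (per-group n, mean, sd, median, q25, q75).
#' @export
compare_groups <- function(covariate, assign, test = c("f_test", "kruskal_wallis")) {
  test <- match.arg(test)
  if (is.data.frame(covariate)) {
    num <- setdiff(names(covariate), "patient_id")[1]
    cov_tbl <- tibble::tibble(patient_id = as.character(covariate$patient_id),
                              value = covariate[[num]])
  } else {
    cov_tbl <- tibble::tibble(patient_id = names(covariate), value = unname(covariate))
  }
  d <- dplyr::inner_join(cov_tbl, assign[, c("patient_id", "class")], by = "patient_id")
  d <- d[!is.na(d$value), , drop = FALSE]
  sizes <- table(d$class)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with fewer than 2 observations: ",
            paste(small, collapse = ", "))
    d <- d[!d$class %in% as.integer(small), , drop = FALSE]
  }
  if (dplyr::n_distinct(d$class) < 2) {
    stop("at least two groups with 2+ observations are required", call. = FALSE)
  }
  d$group <- factor(d$class)
  descr <- dplyr::summarise(
    dplyr::group_by(d, class = .data$class),
    n = dplyr::n(), mean = mean(.data$value), sd = sd(.data$value),
    median = median(.data$value),
    q25 = quantile(.data$value, .25, names = FALSE),
    q75 = quantile(.data$value, .75, names = FALSE),
    .groups = "drop"
  )
  if (test == "f_test") {
    if (isTRUE(all.equal(var(d$value), 0)) || sd(d$value) == 0) {
      return(list(statistic = NA_real_, p_value = NA_real_, df = NULL,
                  method = "one-way ANOVA F-test (undefined: constant values)",
                  descriptives = descr))
    }
    at <- anova(lm(value ~ group, data = d))
    list(statistic = at$`F value`[1], p_value = at$`Pr(>F)`[1],
         df = c(at$Df[1], at$Df[2]), method = "one-way ANOVA F-test",
         descriptives = descr)
  } else {
    kt <- kruskal.test(d$value, d$group)
    list(statistic = unname(kt$statistic), p_value = kt$p.value,
         df = unname(kt$parameter), method = "Kruskal-Wallis rank sum test",
         descriptives = descr)
  }
}

#' Detrended Q-Q (worm) data for randomized quantile residuals
#'
#' Computes one randomized quantile residual per observation under each
#' patient's modally assigned class, with the random intercept fixed at its
#' posterior mean under that class; sorts them against standard-normal
#' plotting positions and returns sample-minus-theoretical deviations.
#'
#' @param data a cohort tibble.
#' @param model a [hurdle_mixture()] or `hurdletraj_fit` (the fit supplies
#'   posteriors; otherwise they are recomputed from the model).
#' @param w optional responsibility matrix; recomputed when missing.
#' @param seed seed for the point-mass randomization.
#' @return a tibble with columns `theoretical_quantile`,
#'   `detrended_deviation` (and `residual`), one row per observation.
#' @export
residual_diagnostics <- function(data, model, w = NULL, seed = 1) {
  if (inherits(model, "hurdletraj_fit")) {
    if (is.null(w)) w <- model$posteriors
    model <- model$model
  }
  stopifnot(inherits(model, "hurdle_mixture"))
  if (nrow(data) == 0) {
    return(tibble::tibble(theoretical_quantile = numeric(0),
                          detrended_deviation = numeric(0),
                          residual = numeric(0)))
  }
  idx <- cohort_index(data)
  gh <- gh_rule(model$ri$n_nodes)
  if (is.null(w)) {
    w <- posteriors_from_loglik(loglik_matrix(idx, model, gh), model$pi,
                                idx$patients)$w
  }
  cls <- max.col(w, ties.method = "first")
  # posterior-mean intercept per patient under the assigned class
  egam <- numeric(idx$n_pat)
  mu <- numeric(idx$n_obs); sig <- numeric(idx$n_obs); nu <- numeric(idx$n_obs)
  for (g in sort(unique(cls))) {
    res <- class_loglik_cohort(idx, model$classes[[g]], model$ri, gh)
    sel_p <- cls == g
    egam[sel_p] <- res$egamma[sel_p]
    sel_o <- sel_p[idx$pid]
    pred <- evaluate_predictors(model$classes[[g]], idx$day[sel_o])
    mu[sel_o] <- pred$mu; sig[sel_o] <- pred$sigma; nu[sel_o] <- pred$nu
  }
  set.seed(seed)
  r <- quantile_residual(idx$hours, mu + egam[idx$pid], sig, nu)
  n <- length(r)
  theo <- qnorm(ppoints(n))
  tibble::tibble(
    theoretical_quantile = theo,
    detrended_deviation = sort(r) - theo,
    residual = sort(r)
  )
}

#' Simulation envelope for the worm plot
#'
#' Simulates `n_sim` standard-normal residual sets of size `n`, computes
#' their detrended deviation curves, and returns the pointwise envelope plus
#' the critical value of the maximum absolute deviation at the requested
#' simultaneous level.
#'
#' @param n number of residuals.
#' @param n_sim number of null simulations (default 200).
#' @param level simultaneous coverage level (default 0.95).
#' @param seed RNG seed.
#' @return a list: `pointwise` (tibble `theoretical_quantile`, `lower`,
#'   `upper`) and `max_abs_critical`.
#' @export
worm_envelope <- function(n, n_sim = 200, level = 0.95, seed = 1) {
  set.seed(seed)
  theo <- qnorm(ppoints(n))
  dev <- matrix(0, n_sim, n)
  maxdev <- numeric(n_sim)
  for (b in seq_len(n_sim)) {
    d <- sort(rnorm(n)) - theo
    dev[b, ] <- d
    maxdev[b] <- max(abs(d))
  }
  list(
    pointwise = tibble::tibble(
      theoretical_quantile = theo,
      lower = apply(dev, 2, quantile, probs = (1 - level) / 2),
      upper = apply(dev, 2, quantile, probs = 1 - (1 - level) / 2)
    ),
    max_abs_critical = quantile(maxdev, level, names = FALSE)
  )
}

#' Model-based simulation envelope for plug-in worm plots
#'
#' The residuals of [residual_diagnostics()] condition on the modally
#' assigned class and the plug-in posterior-mean intercept, so even under a
#' correctly specified model their worm curve is not exactly that of i.i.d.
#' standard normals. This envelope replicates the whole pipeline: cohorts
#' are simulated from the model, diagnosed with the same plug-in rule, and
#' the detrended deviation curves collected.
#'
#' @param model a [hurdle_mixture()] or `hurdletraj_fit`.
#' @param n_patients cohort size per replicate (match the data under test).
#' @param n_days days per patient.
#' @param n_sim number of replicates (default 99).
#' @param level simultaneous coverage level (default 0.95).
#' @param seed RNG seed.
#' @return a list: `pointwise` (tibble `theoretical_quantile`, `lower`,
#'   `upper`) and `max_abs_critical` (critical value for the maximum
#'   absolute deviation).
#' @export
worm_envelope_model <- function(model, n_patients, n_days = 90, n_sim = 99,
                                level = 0.95, seed = 1) {
  if (inherits(model, "hurdletraj_fit")) model <- model$model
  sc <- simulation_scenario(model$classes, model$pi, model$ri$sigma_gamma,
                            n_patients = n_patients, n_days = n_days)
  n <- n_patients * n_days
  dev <- matrix(0, n_sim, n)
  maxdev <- numeric(n_sim)
  for (b in seq_len(n_sim)) {
    simb <- simulate_cohort(sc, seed = seed + b)
    wormb <- residual_diagnostics(simb$data, model, seed = seed + n_sim + b)
    dev[b, ] <- wormb$detrended_deviation
    maxdev[b] <- max(abs(dev[b, ]))
  }
  list(
    pointwise = tibble::tibble(
      theoretical_quantile = qnorm(ppoints(n)),
      lower = apply(dev, 2, quantile, probs = (1 - level) / 2),
      upper = apply(dev, 2, quantile, probs = 1 - (1 - level) / 2)
    ),
    max_abs_critical = quantile(maxdev, level, names = FALSE)
  )
}
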