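#' Latent-class mixture model container
#'
#' A finite mixture of `G` hurdle trajectory classes sharing one random
#' intercept SD. Classes are stored in canonical order: descending mixing
#' proportion, ties broken by the mean-usage intercept.
#'
#' @param classes list of `G` [class_coefficients()] objects.
#' @param pi mixing proportions (non-negative, summing to 1).
#' @param sigma_gamma shared random-intercept SD (hours).
#' @param n_nodes quadrature nodes used when evaluating the model.
#' @return an object of class `hurdle_mixture`.
#' @export
hurdle_mixture <- function(classes, pi, sigma_gamma = 1.5, n_nodes = 21) {
  stopifnot(length(classes) == length(pi), length(classes) >= 1)
  lapply(classes, function(x) stopifnot(inherits(x, "class_coef")))
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-6) {
    stop("`pi` must be non-negative proportions summing to 1", call. = FALSE)
  }
  pi <- pi / sum(pi)
  ord <- order(-pi, vapply(classes, function(x) x$beta_mu[1], 0))
  structure(
    list(classes = classes[ord], pi = pi[ord], G = length(pi),
         ri = random_intercept(sigma_gamma, n_nodes)),
    class = "hurdle_mixture"
  )
}

#' @export
print.hurdle_mixture <- function(x, ...) {
  cat("Latent-class hurdle trajectory model with", x$G, "classes\n")
  cat("sigma_gamma =", signif(x$ri$sigma_gamma, 4), "hours;",
      x$ri$n_nodes, "quadrature nodes\n")
  lbl <- vapply(seq_len(x$G), function(g) {
    if (is.null(x$classes[[g]]$label)) as.character(g) else x$classes[[g]]$label
  }, "")
  cat("pi:", paste(sprintf("%s=%.3f", lbl, x$pi), collapse = ", "), "\n")
  invisible(x)
}

# P x G matrix of per-patient class log-likelihoods
loglik_matrix <- function(idx, model, gh = gh_rule(model$ri$n_nodes)) {
  matrix(vapply(model$classes,
                function(cc) class_loglik_cohort(idx, cc, model$ri, gh)$ll,
                numeric(idx$n_pat)),
         nrow = idx$n_pat)
}

# log-likelihood matrix plus the posterior second moment of the intercept,
# E[gamma^2 | y_i, class g], used for the EM variance-component update
class_eval_all <- function(idx, model, gh) {
  lls <- lapply(model$classes, class_loglik_cohort, idx = idx, ri = model$ri, gh = gh)
  list(llmat = matrix(vapply(lls, `[[`, numeric(idx$n_pat), "ll"), nrow = idx$n_pat),
       eg2 = matrix(vapply(lls, `[[`, numeric(idx$n_pat), "egamma2"), nrow = idx$n_pat))
}

row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

posteriors_from_loglik <- function(llmat, pi, patients = NULL) {
  a <- sweep(llmat, 2, log(pi), "+")
  tot <- row_logsumexp(a)
  bad <- !is.finite(tot)
  if (any(bad)) {
    stop("zero likelihood under every class for patient(s): ",
         paste(head(patients[bad], 5), collapse = ", "), call. = FALSE)
  }
  list(w = exp(a - tot), loglik = sum(tot))
}

#' E-step: posterior class responsibilities
#'
#' Computes `w[i, g] = pi_g exp(l_ig) / sum_g' pi_g' exp(l_ig')` in
#' log-sum-exp form, one row per patient (rows sum to 1).
#'
#' @param data a cohort data frame (`patient_id`, `day`, `hours`).
#' @param model a [hurdle_mixture()].
#' @return matrix of responsibilities with `rownames` the patient ids.
#' @export
e_step <- function(data, model) {
  idx <- cohort_index(data)
  res <- posteriors_from_loglik(loglik_matrix(idx, model), model$pi, idx$patients)
  rownames(res$w) <- as.character(idx$patients)
  res$w
}

weighted_class_ll <- function(idx, wg, coef, ri, gh, trim = 1e-8) {
  keep <- wg >= trim
  if (!any(keep)) return(0)
  sub <- subset_index(idx, keep)
  sum(wg[keep] * class_loglik_cohort(sub, coef, ri, gh)$ll)
}

profile_sigma_gamma <- function(idx, w, classes, sg0, n_nodes, gh, trim = 1e-8) {
  qfun <- function(lsg) {
    ri <- random_intercept(exp(lsg), n_nodes)
    sum(vapply(seq_along(classes), function(g) {
      weighted_class_ll(idx, w[, g], classes[[g]], ri, gh, trim)
    }, 0))
  }
  l0 <- log(max(sg0, 1e-3))
  opt <- optimize(qfun, interval = c(l0 - 0.7, l0 + 0.7), maximum = TRUE, tol = 5e-3)
  if (opt$objective > qfun(l0)) exp(opt$maximum) else sg0
}

#' M-step: update proportions, class coefficients and the intercept SD
#'
#' Proportions are the column means of the responsibilities; each class is
#' refit by [fit_weighted_class()] warm-started from its current
#' coefficients; `sigma_gamma` is updated by a 1-D profile maximization of
#' the weighted log-likelihood (coordinate-wise, shared across classes).
#'
#' @inheritParams e_step
#' @param w responsibility matrix from [e_step()].
#' @param model the current [hurdle_mixture()].
#' @return the updated `hurdle_mixture`, with attribute `"degenerate"` set
#'   to the indices of classes whose effective size fell below 1 patient.
#' @export
m_step <- function(data, w, model) {
  idx <- cohort_index(data)
  m_step_idx(idx, w, model, gh_rule(model$ri$n_nodes))$model
}

m_step_idx <- function(idx, w, model, gh, inner_maxit = 60, trim = 1e-8,
                       update_sigma = TRUE) {
  stopifnot(nrow(w) == idx$n_pat, ncol(w) == model$G)
  pi_new <- colMeans(w)
  degenerate <- which(colSums(w) < 1)
  classes <- model$classes
  fits_ok <- TRUE
  if (length(degenerate) == 0) {
    for (g in seq_len(model$G)) {
      f <- fit_weighted_class_idx(idx, w[, g], model$ri, classes[[g]], gh,
                                  inner_maxit = inner_maxit, trim = trim)
      classes[[g]] <- f$coef
      fits_ok <- fits_ok && !f$degenerate
    }
    sg <- model$ri$sigma_gamma
    if (update_sigma && sg > 0) {
      sg <- profile_sigma_gamma(idx, w, classes, sg, model$ri$n_nodes, gh, trim)
    }
  } else {
    sg <- model$ri$sigma_gamma
    fits_ok <- FALSE
  }
  new_model <- structure(
    list(classes = classes, pi = pi_new, G = model$G,
         ri = random_intercept(sg, model$ri$n_nodes)),
    class = "hurdle_mixture"
  )
  attr(new_model, "degenerate") <- degenerate
  list(model = new_model, ok = fits_ok && length(degenerate) == 0)
}

#' EM control settings
#'
#' @param deviance_tol absolute stopping threshold on the per-cycle reduction
#'   of the deviance `D = -2 log L` (default 0.3).
#' @param max_outer maximum outer EM cycles per restart.
#' @param n_restarts number of random restarts.
#' @param n_nodes quadrature nodes.
#' @param inner_maxit quasi-Newton cap per class refit (a partial,
#'   generalized-EM M-step: each refit still only improves its class).
#' @param trim responsibilities below this are dropped from a class's
#'   weighted fit.
#' @param verbose print per-cycle deviance progress.
#' @return a list of settings for [fit_mixture()].
#' @export
em_control <- function(deviance_tol = 0.3, max_outer = 100, n_restarts = 10,
                       n_nodes = 21, inner_maxit = 15, trim = 1e-8,
                       verbose = FALSE) {
  list(deviance_tol = deviance_tol, max_outer = max_outer,
       n_restarts = n_restarts, n_nodes = n_nodes,
       inner_maxit = inner_maxit, trim = trim, verbose = verbose)
}

#' Fit the latent-class hurdle trajectory mixture by weighted EM
#'
#' Estimates a `G`-class mixture by nonparametric maximum likelihood:
#' repeated EM runs from random responsibility perturbations of the
#' single-class fit, stopping a run when the deviance reduction falls below
#' `deviance_tol`, and keeping the converged run with the lowest deviance.
#'
#' @param data a cohort data frame (`patient_id`, `day`, `hours`).
#' @param G number of latent classes (`>= 1`).
#' @param control settings from [em_control()].
#' @param seed integer seed controlling restarts (and nothing else).
#' @param sigma_gamma optional fixed random-intercept SD; estimated when
#'   `NULL`.
#' @return an object of class `hurdletraj_fit`: elements `model`
#'   ([hurdle_mixture()]), `posteriors`, `loglik`, `deviance`,
#'   `loglik_path`, `converged`, `n_outer_iter`, `restarts` (per-restart
#'   diagnostics), `seed`, `n_patients`.
#' @export
fit_mixture <- function(data, G, control = em_control(), seed = 1,
                        sigma_gamma = NULL) {
  stopifnot(G >= 1)
  idx <- cohort_index(data)
  gh <- gh_rule(control$n_nodes)
  estimate_sg <- is.null(sigma_gamma)

  # single-class base fit (EM initialization)
  set.seed(seed)
  w1 <- rep(1, idx$n_pat)
  sg <- if (estimate_sg) NA_real_ else sigma_gamma
  init <- init_class(idx, w1)
  if (estimate_sg) {
    # moment start: SD of per-patient mean residuals on attempted days
    mu_hat <- poly_eval(init$beta_mu, idx$day[idx$pos])
    pm <- rowsum(idx$y_pos - mu_hat, idx$pid_pos) /
      tabulate(idx$pid_pos, idx$n_pat)
    sg <- max(sd(pm, na.rm = TRUE), 0.2)
  }
  ri <- random_intercept(sg, control$n_nodes)
  base <- fit_weighted_class_idx(idx, w1, ri, init, gh,
                                 inner_maxit = control$inner_maxit)
  if (estimate_sg) {
    # alternate class refits with the EM variance-component update for sg
    for (cycle in 1:4) {
      ev <- class_loglik_cohort(idx, base$coef, ri, gh)
      sg <- sqrt(mean(ev$egamma2))
      ri <- random_intercept(sg, control$n_nodes)
      base <- fit_weighted_class_idx(idx, w1, ri, base$coef, gh,
                                     inner_maxit = control$inner_maxit)
    }
  }

  if (G == 1) {
    model <- hurdle_mixture(list(base$coef), 1, sg, control$n_nodes)
    ll <- sum(class_loglik_cohort(idx, model$classes[[1]], model$ri, gh)$ll)
    w <- matrix(1, idx$n_pat, 1, dimnames = list(as.character(idx$patients), NULL))
    return(new_fit(model, w, ll, ll_path = ll, converged = base$converged,
                   n_outer = 1L, restarts = NULL, seed = seed, idx = idx))
  }

  restart_log <- list()
  best <- NULL
  for (r in seq_len(control$n_restarts)) {
    set.seed(seed + r)
    model <- structure(
      list(classes = rep(list(base$coef), G), pi = rep(1 / G, G), G = G,
           ri = random_intercept(sg, control$n_nodes)),
      class = "hurdle_mixture"
    )
    aborted_sub <- FALSE
    if (idx$n_pat > 600) {
      # separate the classes cheaply on a patient subsample before touching
      # the full cohort; the Dirichlet perturbation happens on the subsample
      n_sub <- max(300L, ceiling(0.15 * idx$n_pat))
      keep <- logical(idx$n_pat)
      keep[sample.int(idx$n_pat, n_sub)] <- TRUE
      sub_idx <- subset_index(idx, keep)
      w_s <- matrix(stats::rexp(n_sub * G), n_sub, G)
      w_s <- w_s / rowSums(w_s)
      dev_prev_s <- Inf
      for (it_s in seq_len(control$max_outer)) {
        ms <- m_step_idx(sub_idx, w_s, model, gh,
                         inner_maxit = control$inner_maxit,
                         trim = control$trim, update_sigma = FALSE)
        if (length(attr(ms$model, "degenerate")) > 0) {
          aborted_sub <- TRUE
          break
        }
        model <- ms$model
        es_s <- posteriors_from_loglik(loglik_matrix(sub_idx, model, gh),
                                       model$pi, sub_idx$patients)
        w_s <- es_s$w
        dev_s <- -2 * es_s$loglik
        if (it_s > 1 && (dev_prev_s - dev_s) < control$deviance_tol) break
        dev_prev_s <- dev_s
      }
      if (aborted_sub) {
        restart_log[[r]] <- tibble::tibble(
          restart = r, deviance = NA_real_, converged = FALSE,
          aborted = TRUE, n_outer_iter = 0L
        )
        next
      }
      w <- posteriors_from_loglik(loglik_matrix(idx, model, gh), model$pi,
                                  idx$patients)$w
    } else {
      w <- matrix(stats::rexp(idx$n_pat * G), idx$n_pat, G)
      w <- w / rowSums(w)
    }
    ll_path <- numeric(0)
    dev_prev <- Inf
    converged <- FALSE
    aborted <- FALSE
    it <- 0
    while (it < control$max_outer) {
      it <- it + 1
      ms <- m_step_idx(idx, w, model, gh, inner_maxit = control$inner_maxit,
                       trim = control$trim, update_sigma = FALSE)
      if (length(attr(ms$model, "degenerate")) > 0) {
        aborted <- TRUE
        break
      }
      model <- ms$model
      ev <- class_eval_all(idx, model, gh)
      es <- posteriors_from_loglik(ev$llmat, model$pi, idx$patients)
      w <- es$w
      if (estimate_sg) {
        # EM update of the shared intercept SD from the posterior second
        # moment of gamma (ascent step; see the methods vignette)
        model$ri <- random_intercept(sqrt(mean(rowSums(w * ev$eg2))),
                                     control$n_nodes)
      }
      ll_path <- c(ll_path, es$loglik)
      dev <- -2 * es$loglik
      if (isTRUE(control$verbose)) {
        message(sprintf("restart %d cycle %3d: deviance %.2f (sg %.3f) [%s]",
                        r, it, dev, model$ri$sigma_gamma,
                        format(Sys.time(), "%H:%M:%S")))
      }
      if (it > 1 && (dev_prev - dev) < control$deviance_tol) {
        converged <- TRUE
        break
      }
      dev_prev <- dev
    }
    dev_final <- if (length(ll_path)) -2 * ll_path[length(ll_path)] else NA_real_
    restart_log[[r]] <- tibble::tibble(
      restart = r, deviance = dev_final, converged = converged,
      aborted = aborted, n_outer_iter = it
    )
    if (!aborted) {
      better <- is.null(best) ||
        (converged && !best$converged) ||
        (converged == best$converged && dev_final < best$deviance)
      if (better) {
        best <- list(model = model, w = w, loglik = ll_path[length(ll_path)],
                     ll_path = ll_path, converged = converged,
                     deviance = dev_final, n_outer = it, seed_used = seed + r)
      }
    }
  }
  restarts <- dplyr::bind_rows(restart_log)
  if (is.null(best)) {
    stop("no EM restart produced a usable fit; per-restart diagnostics:\n",
         paste(utils::capture.output(print(restarts)), collapse = "\n"),
         call. = FALSE)
  }

  # canonical relabeling: descending pi, ties by mean-usage intercept
  ord <- order(-best$model$pi,
               vapply(best$model$classes, function(x) x$beta_mu[1], 0))
  model <- structure(
    list(classes = best$model$classes[ord], pi = best$model$pi[ord], G = G,
         ri = best$model$ri),
    class = "hurdle_mixture"
  )
  w <- best$w[, ord, drop = FALSE]
  rownames(w) <- as.character(idx$patients)
  new_fit(model, w, best$loglik, best$ll_path, best$converged, best$n_outer,
          restarts, seed, idx)
}

new_fit <- function(model, w, ll, ll_path, converged, n_outer, restarts,
                    seed, idx) {
  structure(
    list(model = model, posteriors = w, loglik = ll, deviance = -2 * ll,
         loglik_path = ll_path, converged = converged,
         n_outer_iter = n_outer, restarts = restarts, seed = seed,
         n_patients = idx$n_pat, n_obs = idx$n_obs),
    class = "hurdletraj_fit"
  )
}

#' @export
print.hurdletraj_fit <- function(x, ...) {
  cat("Latent-class hurdle trajectory fit\n")
  cat(sprintf("  G = %d classes, %d patients, %d observations\n",
              x$model$G, x$n_patients, x$n_obs))
  cat(sprintf("  deviance = %.1f (AIC %.1f), %s after %d outer iterations\n",
              x$deviance, information_criterion(x),
              if (x$converged) "converged" else "NOT converged",
              x$n_outer_iter))
  print(x$model)
  invisible(x)
}

#' @export
logLik.hurdletraj_fit <- function(object, ...) {
  structure(object$loglik, df = n_mixture_params(object$model$G),
            class = "logLik")
}

# parameter count: 9 fixed coefficients per class, G-1 free proportions,
# 1 for the shared intercept SD
n_mixture_params <- function(G) 9L * G + (G - 1L) + 1L

#' Generalized Akaike information criterion
#'
#' `penalty * m - 2 log L` with `m` the number of estimated parameters
#' (9 coefficients per class, `G - 1` proportions, one intercept SD).
#' `penalty = 2` gives the AIC; `penalty = log(n)` a BIC-flavored GAIC.
#'
#' @param fit a `hurdletraj_fit`.
#' @param penalty per-parameter penalty.
#' @return a single number.
#' @export
information_criterion <- function(fit, penalty = 2) {
  stopifnot(inherits(fit, "hurdletraj_fit"))
  penalty * n_mixture_params(fit$model$G) - 2 * fit$loglik
}

#' @export
AIC.hurdletraj_fit <- function(object, ..., k = 2) information_criterion(object, k)

#' Relative entropy of the posterior classification
#'
#' `1 - sum_i sum_g -w_ig log w_ig / (n log G)`: 1 means perfectly separated
#' classes (one-hot posteriors), 0 uniform posteriors.
#'
#' @param w responsibility matrix (rows sum to 1).
#' @param G number of classes (`>= 2`).
#' @return a number in `[0, 1]`.
#' @export
relative_entropy <- function(w, G = ncol(w)) {
  if (G < 2) stop("relative entropy is undefined for G = 1", call. = FALSE)
  h <- ifelse(w > 0, -w * log(w), 0)
  1 - sum(h) / (nrow(w) * log(G))
}
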