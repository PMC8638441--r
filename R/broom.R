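coef_tibble <- function(model) {
  purrr::imap_dfr(model$classes, function(cc, g) {
    tibble::tibble(
      class = g,
      label = if (is.null(cc$label)) as.character(g) else cc$label,
      parameter = rep(c("mu", "log_sigma", "logit_nu"), each = 3),
      term = rep(c("intercept", "day", "day2"), 3),
      estimate = c(cc$beta_mu, cc$beta_logsigma, cc$beta_logitnu)
    )
  })
}

#' Tidy a latent-class hurdle trajectory fit
#'
#' One row per class, predictor and polynomial term, with estimates on the
#' raw day scale.
#'
#' @param x a `hurdletraj_fit`.
#' @param ... unused.
#' @return a tibble with columns `class`, `label`, `parameter`
#'   (`mu`/`log_sigma`/`logit_nu`), `term`, `estimate`, `pi`.
#' @exportS3Method generics::tidy
#' @export
tidy.hurdletraj_fit <- function(x, ...) {
  out <- coef_tibble(x$model)
  out$pi <- x$model$pi[out$class]
  out
}

#' Glance at a latent-class hurdle trajectory fit
#'
#' @inheritParams tidy.hurdletraj_fit
#' @return a one-row tibble: `G`, `n_patients`, `n_obs`, `logLik`,
#'   `deviance`, `AIC`, `relative_entropy` (`NA` for `G = 1`),
#'   `sigma_gamma`, `n_outer_iter`, `converged`.
#' @exportS3Method generics::glance
#' @export
glance.hurdletraj_fit <- function(x, ...) {
  tibble::tibble(
    G = x$model$G,
    n_patients = x$n_patients,
    n_obs = x$n_obs,
    logLik = x$loglik,
    deviance = x$deviance,
    AIC = information_criterion(x),
    relative_entropy = if (x$model$G >= 2) relative_entropy(x$posteriors) else NA_real_,
    sigma_gamma = x$model$ri$sigma_gamma,
    n_outer_iter = x$n_outer_iter,
    converged = x$converged
  )
}

#' Augment patient records with posterior class membership
#'
#' @inheritParams tidy.hurdletraj_fit
#' @return a tibble with one row per patient: `patient_id`, `class` (modal),
#'   `posterior_prob`, and one `.w<g>` column per class.
#' @exportS3Method generics::augment
#' @export
augment.hurdletraj_fit <- function(x, ...) {
  w <- x$posteriors
  out <- modal_assign(w)
  wt <- tibble::as_tibble(w, .name_repair = ~ paste0(".w", seq_len(ncol(w))))
  dplyr::bind_cols(out, wt)
}
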