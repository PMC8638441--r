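#' Write / read a fitted mixture model as JSON
#'
#' Serializes the mixture (proportions, per-class coefficient triples on the
#' raw day scale, the shared intercept SD, quadrature setting) plus fit
#' metadata, with full double precision so the round trip is lossless.
#'
#' @param x a `hurdle_mixture` or `hurdletraj_fit`.
#' @param path file path to write to.
#' @return `write_model` returns `path` invisibly; `read_model` returns a
#'   [hurdle_mixture()] with fit metadata in `attr(, "fit_meta")`.
#' @export
write_model <- function(x, path) {
  fit_meta <- NULL
  if (inherits(x, "hurdletraj_fit")) {
    fit_meta <- list(seed = x$seed, deviance = x$deviance,
                     loglik = x$loglik, n_outer_iter = x$n_outer_iter,
                     converged = x$converged, n_patients = x$n_patients)
    x <- x$model
  }
  stopifnot(inherits(x, "hurdle_mixture"))
  doc <- list(
    schema_version = 1L,
    G = x$G,
    pi = x$pi,
    sigma_gamma = x$ri$sigma_gamma,
    n_nodes = x$ri$n_nodes,
    classes = lapply(x$classes, function(cc) {
      list(label = cc$label, beta_mu = cc$beta_mu,
           beta_logsigma = cc$beta_logsigma, beta_logitnu = cc$beta_logitnu)
    }),
    fit = fit_meta
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(doc$schema_version) || doc$schema_version != 1) {
    stop("unrecognized model schema", call. = FALSE)
  }
  classes <- lapply(doc$classes, function(cc) {
    class_coefficients(cc$beta_mu, cc$beta_logsigma, cc$beta_logitnu,
                       label = cc$label)
  })
  model <- hurdle_mixture(classes, unlist(doc$pi), doc$sigma_gamma, doc$n_nodes)
  attr(model, "fit_meta") <- doc$fit
  model
}
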