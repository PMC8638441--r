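#' Per-class quadratic coefficients for the three linked predictors
#'
#' A latent class is described by three quadratic-in-time linear predictors on
#' the raw day scale `t` in 1..90: the conditional mean usage
#' `mu(t) = b[1] + b[2] t + b[3] t^2` (identity link, hours), the day-to-day
#' standard deviation `sigma(t)` (log link, log-hours scale coefficients), and
#' the non-attempt probability `nu(t)` (logit link).
#'
#' @param beta_mu,beta_logsigma,beta_logitnu numeric length-3 coefficient
#'   vectors `(intercept, linear, quadratic)` on the raw day scale.
#' @param label optional class label (e.g. `"A"`).
#' @return an object of class `class_coef`.
#' @export
class_coefficients <- function(beta_mu, beta_logsigma, beta_logitnu, label = NULL) {
  for (b in list(beta_mu, beta_logsigma, beta_logitnu)) {
    if (length(b) != 3 || any(!is.finite(b))) {
      stop("each coefficient vector must be 3 finite numbers (intercept, linear, quadratic)",
           call. = FALSE)
    }
  }
  structure(
    list(beta_mu = as.numeric(beta_mu),
         beta_logsigma = as.numeric(beta_logsigma),
         beta_logitnu = as.numeric(beta_logitnu),
         label = label),
    class = "class_coef"
  )
}

#' @export
print.class_coef <- function(x, ...) {
  cat("<class_coef", if (!is.null(x$label)) paste0(" '", x$label, "'"), ">\n", sep = "")
  m <- rbind(mu = x$beta_mu, `log sigma` = x$beta_logsigma, `logit nu` = x$beta_logitnu)
  colnames(m) <- c("intercept", "t", "t^2")
  print(signif(m, 4))
  invisible(x)
}

poly_eval <- function(beta, t) beta[1] + beta[2] * t + beta[3] * t^2

# Internal time standardization for optimizer conditioning: s = (t - 45.5)/26.
# All reported coefficients live on the raw day scale; these convert exactly.
.t_center <- 45.5
.t_scale <- 26

std_time <- function(t) (t - .t_center) / .t_scale

raw_to_std <- function(a, cc = .t_center, d = .t_scale) {
  c(a[1] + a[2] * cc + a[3] * cc^2,
    a[2] * d + 2 * a[3] * cc * d,
    a[3] * d^2)
}

std_to_raw <- function(b, cc = .t_center, d = .t_scale) {
  c(b[1] - b[2] * cc / d + b[3] * cc^2 / d^2,
    b[2] / d - 2 * b[3] * cc / d^2,
    b[3] / d^2)
}

#' Evaluate the three linked predictors of a class at given days
#'
#' Applies the inverse links to the quadratic predictors: identity for the
#' mean, exponential for the standard deviation, inverse-logit for the
#' non-attempt probability.
#'
#' @param coef a [class_coefficients()] object.
#' @param t vector of days (raw scale, `>= 0`).
#' @return a tibble with columns `day`, `mu` (hours), `sigma` (hours),
#'   `nu` (probability of a non-attempt).
#' @examples
#' cc <- class_coefficients(c(7, 0, 0), c(0, 0, 0), c(qlogis(0.1), 0, 0))
#' evaluate_predictors(cc, c(1, 45, 90))
#' @export
evaluate_predictors <- function(coef, t) {
  stopifnot(inherits(coef, "class_coef"))
  if (any(t < 0)) stop("days must be non-negative", call. = FALSE)
  tibble::tibble(
    day = t,
    mu = poly_eval(coef$beta_mu, t),
    sigma = exp(poly_eval(coef$beta_logsigma, t)),
    nu = plogis(poly_eval(coef$beta_logitnu, t))
  )
}
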