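#' Random-intercept specification
#'
#' The patient random intercept acts on the mean-usage predictor only and is
#' shared across classes. Its marginal integral is evaluated by adaptive
#' Gauss-Hermite quadrature: nodes are recentred and rescaled per patient
#' using the Gaussian part of the integrand, so the rule stays accurate when
#' 90 daily observations concentrate the intercept posterior far below the
#' prior scale.
#'
#' @param sigma_gamma standard deviation of the patient intercept (hours,
#'   `>= 0`); `0` disables the random effect.
#' @param n_nodes odd number of quadrature nodes (default 21).
#' @return an object of class `random_intercept`.
#' @export
random_intercept <- function(sigma_gamma = 1.5, n_nodes = 21) {
  if (!is.finite(sigma_gamma) || sigma_gamma < 0) {
    stop("`sigma_gamma` must be a non-negative number of hours", call. = FALSE)
  }
  if (n_nodes < 1 || n_nodes %% 2 != 1) {
    stop("`n_nodes` must be an odd count >= 1", call. = FALSE)
  }
  structure(list(sigma_gamma = sigma_gamma, n_nodes = as.integer(n_nodes)),
            class = "random_intercept")
}

gh_rule <- function(n_nodes) {
  if (n_nodes == 1) return(list(x = 0, logw = 0.5 * log(pi)))
  gh <- pracma::gaussHermite(n_nodes)
  list(x = gh$x, logw = log(gh$w))
}

# clamp the logit-nu predictor so fitted hurdle probabilities stay strictly
# interior; logit(1e-8) ~ -18.42
.eta_nu_max <- qlogis(1 - 1e-8)

# Precomputed cohort layout shared by all likelihood work. Observations are
# split into the hurdle part (all days) and the positive part (attempted
# days, sorted by patient) with quadratic design matrices on standardized
# time s = (t - 45.5)/26.
cohort_index <- function(data) {
  stopifnot(all(c("patient_id", "day", "hours") %in% names(data)))
  if (nrow(data) == 0) stop("cohort has no observations", call. = FALSE)
  data <- dplyr::arrange(data, .data$patient_id, .data$day)
  patients <- unique(data$patient_id)
  pid <- match(data$patient_id, patients)
  s <- std_time(data$day)
  X <- cbind(1, s, s * s)
  pos <- data$hours > 0
  list(
    patients = patients,
    n_pat = length(patients),
    n_obs = nrow(data),
    day = data$day,
    hours = data$hours,
    pid = pid,
    attempt = as.numeric(pos),
    X = X,
    pos = pos,
    Xp = X[pos, , drop = FALSE],
    y_pos = data$hours[pos],
    pid_pos = pid[pos]
  )
}

# Per-patient log-likelihood under one class: hurdle factor (exact, no random
# effect) + positive-part factor marginalized over the intercept.
# Returns list(ll, hurdle_ll, tn_ll, egamma, dmu, dlogsigma).
class_loglik_cohort <- function(idx, coef, ri, gh = gh_rule(ri$n_nodes),
                                want_grad = FALSE) {
  b_nu <- raw_to_std(coef$beta_logitnu)
  eta_nu <- drop(idx$X %*% b_nu)
  eta_nu <- pmin(pmax(eta_nu, -.eta_nu_max), .eta_nu_max)
  # log nu for zeros, log(1 - nu) for attempts, both in log space
  lh <- ifelse(idx$attempt == 1,
               plogis(-eta_nu, log.p = TRUE),
               plogis(eta_nu, log.p = TRUE))
  hurdle_ll <- as.numeric(rowsum(lh, idx$pid, reorder = TRUE))

  b_mu <- raw_to_std(coef$beta_mu)
  b_ls <- raw_to_std(coef$beta_logsigma)
  mu <- drop(idx$Xp %*% b_mu)
  logsig <- drop(idx$Xp %*% b_ls)
  res <- tn_marginal_cpp(mu, logsig, idx$y_pos, idx$pid_pos - 1L, idx$n_pat,
                         gh$x, gh$logw, ri$sigma_gamma, want_grad)
  list(ll = hurdle_ll + res$ll, hurdle_ll = hurdle_ll, tn_ll = res$ll,
       egamma = res$egamma, egamma2 = res$egamma2,
       dmu = res$dmu, dlogsigma = res$dlogsigma)
}

#' Marginal log-likelihood of one patient trajectory under one class
#'
#' Computes `log Int prod_j f_TNH(y_j; mu_j + gamma, sigma_j, nu_j) dN(gamma;
#' 0, sigma_gamma^2)` by adaptive Gauss-Hermite quadrature in log-sum-exp
#' form. With `sigma_gamma = 0` this reduces exactly to the sum of per-day
#' [dtnh()] log-densities.
#'
#' @param trajectory a data frame with columns `day` (strictly increasing
#'   integers) and `hours` (non-negative; zeros are non-attempts).
#' @param coef a [class_coefficients()] object.
#' @param ri a [random_intercept()] specification.
#' @return a single log-likelihood value.
#' @export
class_loglik_patient <- function(trajectory, coef, ri = random_intercept()) {
  stopifnot(inherits(coef, "class_coef"), inherits(ri, "random_intercept"))
  if (nrow(trajectory) == 0) stop("empty trajectory", call. = FALSE)
  if (is.unsorted(trajectory$day, strictly = TRUE)) {
    stop("`day` must be strictly increasing within a trajectory", call. = FALSE)
  }
  if (any(trajectory$hours < 0)) stop("negative hours are not valid", call. = FALSE)
  df <- tibble::tibble(patient_id = "p", day = trajectory$day, hours = trajectory$hours)
  class_loglik_cohort(cohort_index(df), coef, ri)$ll[1]
}
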