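#' @keywords internal
subset_index <- function(idx, keep_pat) {
  if (all(keep_pat)) return(idx)
  obs <- keep_pat[idx$pid]
  new_id <- cumsum(keep_pat)
  pid <- new_id[idx$pid[obs]]
  pos <- idx$pos[obs]
  list(
    patients = idx$patients[keep_pat],
    n_pat = sum(keep_pat),
    n_obs = sum(obs),
    day = idx$day[obs],
    hours = idx$hours[obs],
    pid = pid,
    attempt = idx$attempt[obs],
    X = idx$X[obs, , drop = FALSE],
    pos = pos,
    Xp = idx$X[obs, , drop = FALSE][pos, , drop = FALSE],
    y_pos = idx$hours[obs][pos],
    pid_pos = pid[pos]
  )
}

# crude single-class starting values from weighted summary statistics
init_class <- function(idx, w_pat) {
  w_obs <- w_pat[idx$pid]
  zrate <- sum(w_obs * (1 - idx$attempt)) / sum(w_obs)
  zrate <- min(max(zrate, 1e-4), 1 - 1e-4)
  w_pos <- w_pat[idx$pid_pos]
  if (sum(w_pos) > 0 && length(idx$y_pos) > 3) {
    fit <- stats::lm.wfit(idx$Xp, idx$y_pos, w_pos)
    b_mu <- std_to_raw(fit$coefficients)
    rsd <- sqrt(sum(w_pos * fit$residuals^2) / sum(w_pos))
  } else {
    b_mu <- c(mean(idx$y_pos), 0, 0)
    rsd <- max(sd(idx$y_pos), 0.5)
  }
  class_coefficients(
    beta_mu = b_mu,
    beta_logsigma = c(log(max(rsd, 0.05)), 0, 0),
    beta_logitnu = c(qlogis(zrate), 0, 0)
  )
}

# Weighted single-class fit on a prebuilt cohort index. The hurdle factor is
# maximized exactly by a weighted quadratic logistic GLM; the truncated-normal
# factor (6 coefficients) by BFGS with analytic gradients from the quadrature
# kernel. Patients with weight < trim are dropped from the weighted
# objective (their contribution is numerically negligible).
fit_weighted_class_idx <- function(idx, w_pat, ri, init, gh,
                                   inner_maxit = 60, trim = 1e-8,
                                   se = FALSE) {
  stopifnot(length(w_pat) == idx$n_pat)
  if (any(w_pat < 0) || all(w_pat <= 0)) {
    stop("weights must be non-negative with at least one positive entry", call. = FALSE)
  }
  keep <- w_pat >= trim
  degenerate <- sum(keep) < 2 || sum(w_pat) < 1
  if (sum(keep) == 0) keep <- w_pat > 0
  sub <- subset_index(idx, keep)
  w <- w_pat[keep]
  w_obs <- w[sub$pid]

  # --- hurdle factor: weighted logistic regression on attempt ~ 1 + s + s^2
  b_nu_std <- raw_to_std(init$beta_logitnu)
  glm_fit <- tryCatch(
    suppressWarnings(glm.fit(sub$X, sub$attempt, weights = w_obs,
                             family = quasibinomial(), start = -b_nu_std)),
    error = function(e) NULL
  )
  if (is.null(glm_fit) || any(!is.finite(glm_fit$coefficients))) {
    glm_fit <- tryCatch(
      suppressWarnings(glm.fit(sub$X, sub$attempt, weights = w_obs,
                               family = quasibinomial())),
      error = function(e) NULL
    )
  }
  if (!is.null(glm_fit) && all(is.finite(glm_fit$coefficients))) {
    b_nu_std <- -glm_fit$coefficients # glm models P(attempt); nu = P(no attempt)
  }
  eta_obs <- drop(sub$X %*% b_nu_std)
  clamped <- any(abs(eta_obs) > .eta_nu_max)

  # --- positive part: BFGS over (beta_mu, beta_logsigma) on the std scale
  w_pos <- w[sub$pid_pos]
  par0 <- c(raw_to_std(init$beta_mu), raw_to_std(init$beta_logsigma))
  # fn is evaluated at many line-search trial points where the gradient is
  # not needed, so the kernel is only asked for gradients inside gr
  cache <- new.env(parent = emptyenv())
  eval_par <- function(par, want_grad) {
    if (want_grad && identical(cache$gpar, par)) return(cache$gval)
    if (!want_grad && identical(cache$fpar, par)) return(cache$fval)
    mu <- drop(sub$Xp %*% par[1:3])
    logsig <- drop(sub$Xp %*% par[4:6])
    if (any(logsig > 6) || any(logsig < -10) || any(!is.finite(mu))) {
      val <- list(f = 1e10, g = rep(0, 6))
    } else {
      r <- tn_marginal_cpp(mu, logsig, sub$y_pos, sub$pid_pos - 1L, sub$n_pat,
                           gh$x, gh$logw, ri$sigma_gamma, want_grad)
      f <- -sum(w * r$ll)
      g <- if (want_grad) {
        -c(crossprod(sub$Xp, w_pos * r$dmu), crossprod(sub$Xp, w_pos * r$dlogsigma))
      } else NULL
      if (!is.finite(f)) { f <- 1e10; g <- rep(0, 6) }
      val <- list(f = f, g = g)
    }
    if (want_grad) { cache$gpar <- par; cache$gval <- val }
    else { cache$fpar <- par; cache$fval <- val }
    val
  }
  opt <- optim(par0, fn = function(p) eval_par(p, FALSE)$f,
               gr = function(p) eval_par(p, TRUE)$g,
               method = "BFGS", control = list(maxit = inner_maxit))
  par <- opt$par
  grad_norm <- sqrt(sum(eval_par(par, TRUE)$g^2))

  coef <- class_coefficients(
    beta_mu = std_to_raw(par[1:3]),
    beta_logsigma = std_to_raw(par[4:6]),
    beta_logitnu = std_to_raw(b_nu_std),
    label = init$label
  )

  out <- list(coef = coef,
              converged = opt$convergence == 0 && !degenerate,
              degenerate = degenerate,
              clamped = clamped,
              grad_norm = grad_norm,
              n_inner = opt$counts[["function"]])
  if (se) out$se <- class_fit_se(sub, w, w_obs, w_pos, par, b_nu_std,
                                 function(p) eval_par(p, TRUE))
  out
}

# Asymptotic standard errors on the raw day scale from the observed
# information of the weighted objective (fixed responsibilities).
class_fit_se <- function(sub, w, w_obs, w_pos, par, b_nu_std, eval_par) {
  H <- stats::optimHess(par, fn = function(p) eval_par(p)$f,
                        gr = function(p) eval_par(p)$g)
  V6 <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 6, 6))
  p_att <- plogis(drop(sub$X %*% -b_nu_std)) # P(attempt)
  I3 <- crossprod(sub$X, sub$X * (w_obs * p_att * (1 - p_att)))
  V3 <- tryCatch(solve(I3), error = function(e) matrix(NA_real_, 3, 3))
  M <- rbind(c(1, -.t_center / .t_scale, .t_center^2 / .t_scale^2),
             c(0, 1 / .t_scale, -2 * .t_center / .t_scale^2),
             c(0, 0, 1 / .t_scale^2))
  se_raw <- function(V) sqrt(pmax(diag(M %*% V %*% t(M)), 0))
  tibble::tibble(
    parameter = rep(c("mu", "log_sigma", "logit_nu"), each = 3),
    term = rep(c("intercept", "day", "day2"), 3),
    se = c(se_raw(V6[1:3, 1:3]), se_raw(V6[4:6, 4:6]), se_raw(V3))
  )
}

#' Weighted single-class fit
#'
#' Maximizes the weighted sum of per-patient marginal log-likelihoods
#' `sum_i w_i * l_i(coef)` for one class, as used inside the EM M-step.
#' The Bernoulli hurdle factor separates from the positive part (the random
#' intercept acts on the mean only) and is fit exactly by weighted logistic
#' regression; the mean/scale coefficients are fit by quasi-Newton ascent
#' with analytic gradients.
#'
#' @param data a cohort data frame (`patient_id`, `day`, `hours`).
#' @param weights per-patient weights in `[0, 1]` (order of sorted unique
#'   `patient_id`), at least one positive.
#' @param ri a [random_intercept()] specification.
#' @param init optional [class_coefficients()] starting values; a
#'   moment-based start is used when omitted.
#' @param se if `TRUE`, attach asymptotic standard errors (raw day scale).
#' @param inner_maxit maximum quasi-Newton iterations.
#' @return a list with elements `coef` (a [class_coefficients()] object on
#'   the raw day scale), `converged`, `degenerate` (non-identifiability
#'   flag), `clamped` (hurdle probabilities pushed to the interior boundary),
#'   `grad_norm`, and optionally `se`.
#' @export
fit_weighted_class <- function(data, weights = NULL, ri = random_intercept(),
                               init = NULL, se = FALSE, inner_maxit = 60) {
  idx <- cohort_index(data)
  if (is.null(weights)) weights <- rep(1, idx$n_pat)
  if (any(weights < 0) || all(weights <= 0)) {
    stop("weights must be non-negative with at least one positive entry", call. = FALSE)
  }
  if (is.null(init)) init <- init_class(idx, weights)
  fit_weighted_class_idx(idx, weights, ri, init, gh_rule(ri$n_nodes),
                         inner_maxit = inner_maxit, se = se)
}
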