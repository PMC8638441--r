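---
title: "Modeling daily therapy-adherence trajectories with latent-class hurdle mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling daily therapy-adherence trajectories with latent-class hurdle mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Daily adherence to a device-based therapy such as CPAP produces, per patient,
a 90-day series of hours-of-use in which many days are exact zeros: the
patient never started the device that night. `hurdletraj` models each day as
a two-part (hurdle) outcome. A Bernoulli gate decides whether therapy is
attempted; conditional on an attempt, the time on therapy follows a normal
distribution restricted to positive values (a zero-truncated normal). Zeros
arise *only* from the gate, which matches how device exports record
non-attempts.

For a patient in latent class $g$ on day $t$, the three distributional
parameters each get their own linked quadratic predictor:

$$
\begin{aligned}
\mu(t) &= \beta_{1,0} + \beta_{1,1} t + \beta_{1,2} t^2 + \gamma_i,\\
\log \sigma(t) &= \beta_{2,0} + \beta_{2,1} t + \beta_{2,2} t^2,\\
\operatorname{logit} \nu(t) &= \beta_{3,0} + \beta_{3,1} t + \beta_{3,2} t^2,
\end{aligned}
$$

where $\nu$ is the probability of a non-attempt and
$\gamma_i \sim N(0, \sigma_\gamma^2)$ is a patient random intercept on the
mean only, shared across classes. This is a distributional-regression
("location-scale-shape") class model: classes can differ not just in mean
usage but in how consistently the therapy is attempted and in day-to-day
variability, which is where much of the clinically interesting heterogeneity
lives.

The cohort likelihood is a finite mixture over $G$ classes with proportions
$\pi_g$; per patient the class likelihood is the product of daily hurdle
densities, marginalized over $\gamma_i$. Estimation is nonparametric maximum
likelihood via EM: the E-step computes per-patient responsibilities
$w_{ig}$, the M-step refits each class by responsibility-weighted regression
and updates $\pi$ by averaging responsibilities.

## Parameters that matter

* `sigma_gamma` (hours): the between-patient spread in mean usage within a
  class. Default 1.5 h in the nine-class preset, matching the study the
  preset reproduces. Without it most classes would degenerate into parallel
  constant trajectories distinguished only by level.
* `n_nodes` (default 21, odd): Gauss-Hermite nodes for the intercept
  integral. See the numerical notes below.
* `deviance_tol` (default 0.3, absolute): the EM run stops when the
  deviance $D = -2\log L$ improves by less than this between outer cycles.
  A deliberately lenient threshold: with tens of thousands of observations
  the class trajectories are stable well before the deviance settles to
  machine precision.
* `n_restarts` (default 10): EM is restarted from independent random
  responsibility draws; the converged run with the lowest deviance wins.
* `max_hours` (default 15 h): records above this are treated as device
  artifacts. The reader drops them from the likelihood (days are *not*
  recoded as zeros, since they are unreliable measurements rather than
  non-attempts); the simulator resamples above-cap draws so synthetic
  trajectories stay complete.
* `compliance_hours` (default 4 h): the per-day compliance threshold used
  in post-hoc summaries, the usual US reimbursement convention.

## Numerical choices

**Truncation normalizer in log space.** Every density evaluation needs
$\Pr(X > 0) = \Phi(\mu/\sigma)$. Both tails are evaluated in log space
(`pnorm(log.p = TRUE)` in R), so classes whose mean sits many standard
deviations from zero — in either direction — keep finite, accurate
log-likelihoods. The compiled quadrature kernel evaluates billions of
mid-range $\log\Phi$ and Mills-ratio terms, so there they come from
precomputed cubic-Hermite tables (step $2\times10^{-3}$ on $[-30, 8]$,
interpolation error below $10^{-12}$) with exact asymptotic expansions
outside the table; the tests pin the kernel against `pnorm` to $10^{-13}$.

**Adaptive quadrature.** With 90 days per patient the posterior of
$\gamma_i$ is roughly $\sigma/\sqrt{J}$ wide — an order of magnitude
narrower than its $N(0, \sigma_\gamma^2)$ prior. Prior-scaled Gauss-Hermite
nodes would straddle that peak with one or two points, so nodes are
recentred and rescaled per patient using the Gaussian part of the integrand
(which is exactly quadratic in $\gamma$, making mode and curvature closed
form). With 21 adaptive nodes, doubling the node count changes patient
log-likelihoods by less than $10^{-6}$; the test suite verifies this and
checks small cases against adaptive numeric integration.

**Factorized M-step.** Because the random intercept enters only $\mu$, the
Bernoulli gate factors out of the marginal likelihood. Each class M-step
therefore fits the attempt model exactly by weighted quadratic logistic
regression, and only the six $(\mu, \log\sigma)$ coefficients need
quasi-Newton ascent (BFGS with analytic gradients) over the quadrature
marginal. Time is standardized internally to $(t - 45.5)/26$ for optimizer
conditioning — raw $t^2$ reaches 8100 and ruins the Hessian — and all
reported coefficients are mapped back to the raw day scale exactly.

**Variance-component update.** Inside `fit_mixture`, $\sigma_\gamma$ is
updated each cycle by the EM variance-component step
$\hat\sigma_\gamma^2 = \tfrac1n \sum_{i,g} w_{ig}\,E[\gamma_i^2 \mid y_i, g]$,
whose ingredients fall out of the same quadrature pass as the E-step. The
standalone `m_step()` exposes the equivalent 1-D profile update. Both are
ascent steps, so the marginal log-likelihood is nondecreasing across cycles
(a property the tests assert on every run).

**Initialization and degeneracy.** Each restart starts from per-patient
Dirichlet(1) responsibility draws around the single-class fit — a
reproducible, seed-controlled version of the usual NPML random-start
scheme. On cohorts above 600 patients the perturbed EM first runs on a
random 15% patient subsample until its own deviance criterion is met, and
full-data EM continues from the subsample solution: the diffuse early
cycles are the expensive part, and the subsample reaches class separation
at a fraction of the cost. The M-step itself is partial — the per-class
quasi-Newton refit is capped at 15 iterations — which keeps every cycle an
ascent step (generalized EM) while avoiding needless inner convergence far
from the solution. Patients with responsibility below $10^{-8}$ are trimmed from a
class's weighted refit (their contribution is below $10^{-3}$ log-likelihood
at any tested scale). A class whose effective size falls below one patient
aborts that restart and is reported in the per-restart diagnostics rather
than raised as an error, since occasional non-convergence is expected from
random starts. Fitted hurdle probabilities are kept strictly inside
$(10^{-8}, 1 - 10^{-8})$ so the logit stays finite even when a class has no
observed zeros.

**Model dimension.** The AIC/GAIC parameter count is $m = 9G + (G - 1) + 1$:
nine fixed coefficients per class, free proportions, and the shared
intercept SD. `information_criterion(fit, penalty)` exposes the GAIC;
`penalty = 2` is the AIC.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws a class per patient, an intercept
$\gamma_i$, then daily Bernoulli gates and truncated-normal hours, with
above-cap draws resampled. The nine-class preset `paper_scenario()` encodes
the published coefficient table of a 10,000-patient CPAP study (classes A-I,
proportions .16/.12/.23/.13/.08/.08/.09/.06/.05, $\sigma_\gamma = 1.5$ h)
after undoing the table's printed column scalings; the three-class scenario
used throughout the tests is a smaller caricature — consistent users,
gradual decliners, early dropouts — whose classes are separated by at least
1.5 h in mean level and 2 logits in attempt probability.

The simulator implements the model's own assumptions, so passing recovery
tests shows the estimator works *under those assumptions* — it cannot show
that real adherence data satisfies them. In particular, real non-attempts
cluster in multi-day episodes (illness, travel) where the model assumes
independent daily gates; real usage has heavier tails than the truncated
normal (visible as worm-plot tail dips); and real cohorts have dropout and
missing uploads, which the 90-day complete-follow-up design excludes by
construction.

## Residual diagnostics

Model fit is assessed with randomized quantile residuals through the mixed
discrete-continuous CDF: exact zeros are randomized uniformly within their
point mass, positive hours map through the continuous CDF. Residuals are
computed under each patient's modally assigned class with the intercept at
its posterior mean — a plug-in choice that matches how per-class diagnostics
are read in practice, rather than mixing over the full posterior. The worm
plot (detrended Q-Q) of these residuals is compared against an envelope
built by *replicating the entire pipeline* on cohorts simulated from the
model (`worm_envelope_model()`): because of the plug-in conditioning, the
null curve is not exactly that of i.i.d. standard normals, and a naive
normal envelope would be slightly too narrow. Note the envelope is a 95%
simultaneous band: one well-specified dataset in twenty will poke out of it.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen to finish in minutes while
keeping every property measurable: parameter recovery and model selection
on 500 patients x 90 days (three classes, AIC over $G = 1..5$), class
separation on 2000 patients x 90 days under the nine-class preset, residual
calibration on 200-patient replicates. The published analysis behind the
preset used 10,000 patients; nothing in the implementation is specific to
the smaller sizes.

## Known limitations

* The hurdle gate has no random effect and no serial dependence; runs of
  zeros are fit only through the smooth $\nu(t)$ trend.
* The response is truncated normal; heavy-tailed alternatives (truncated
  $t$) are out of scope, as are spline or fractional-polynomial time
  effects — quadratics keep the class models identifiable and cheap.
* Three-step covariate comparisons ignore classification error (no
  misclassification correction); with 90 days per patient the posterior
  classes are nearly crisp, which is when the uncorrected comparison is
  least biased.
* Likelihood-ratio tests between class counts are not provided; at these
  sample sizes they are degenerate, and AIC/GAIC plus relative entropy are
  the intended selection tools.

## A worked example

```{r, eval = FALSE}
library(hurdletraj)

# simulate a three-class cohort and refit it
cl <- list(
  class_coefficients(c(7.3, 0, 0), c(0, 0, 0), c(-4, 0, 0), label = "consistent"),
  class_coefficients(c(5.8, -0.01, 5e-5), c(log(1.8), 0, 0), c(-2, 0.02, 0),
                     label = "decliner"),
  class_coefficients(c(4.3, -0.02, 1e-4), c(log(1.5), 0, 0), c(0, 0.03, -1e-4),
                     label = "dropout")
)
sc <- simulation_scenario(cl, pi = c(0.5, 0.3, 0.2), sigma_gamma = 1.5,
                          n_patients = 300)
sim <- simulate_cohort(sc, seed = 7)

fit <- fit_mixture(sim$data, G = 3, control = em_control(n_restarts = 2), seed = 1)
glance(fit)
trajectory_table(fit, days = c(1, 45, 90))
autoplot(fit)

worm <- residual_diagnostics(sim$data, fit, seed = 1)
plot_worm(worm)
```
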