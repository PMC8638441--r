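# hurdletraj

Latent-class heteroskedastic hurdle trajectory models for daily
therapy-adherence time series.

## What problem this solves

Patients on device-based therapies (the motivating case is CPAP for
obstructive sleep apnea) generate one usage measurement per day over their
first months of treatment. These series mix two behaviors: whether therapy
was *attempted* on a given day (many days are exact zeros), and *how long*
it was used when attempted — including how variable that duration is from
day to day. Population-level adherence patterns live in all three
dimensions at once.

`hurdletraj` is for biostatisticians and adherence researchers who want to
discover such patterns. Each day is modeled as a hurdle outcome: a
Bernoulli attempt gate with probability $1-\nu(t)$, then a zero-truncated
normal time on therapy. A latent class $g$ specifies quadratic-in-time
linked predictors

$$\mu^{(g)}(t) = \beta_{1,0} + \beta_{1,1}t + \beta_{1,2}t^2 + \gamma_i,\qquad
\log\sigma^{(g)}(t) = \beta_{2,0} + \beta_{2,1}t + \beta_{2,2}t^2,\qquad
\operatorname{logit}\nu^{(g)}(t) = \beta_{3,0} + \beta_{3,1}t + \beta_{3,2}t^2,$$

with a patient random intercept $\gamma_i \sim N(0, \sigma_\gamma^2)$ on the
mean, shared across classes and marginalized by adaptive Gauss-Hermite
quadrature. The mixture $f(y) = \sum_g \pi_g f_g(y)$ is estimated by
weighted EM over per-patient marginal likelihoods (nonparametric maximum
likelihood with mass points), with deviance-based stopping, random
restarts, AIC/GAIC model selection, relative-entropy separation, randomized
quantile residual (worm plot) diagnostics, and three-step post-hoc group
comparison. A simulator generates synthetic cohorts, including a nine-class
preset encoding a published 10,000-patient CPAP analysis.

## A worked example

```r
library(hurdletraj)

cl <- list(
  class_coefficients(c(7.3, 0, 0), c(0, 0, 0), c(-4, 0, 0), label = "consistent"),
  class_coefficients(c(5.8, -0.01, 5e-5), c(log(1.8), 0, 0), c(-2, 0.02, 0),
                     label = "decliner"),
  class_coefficients(c(4.3, -0.02, 1e-4), c(log(1.5), 0, 0), c(0, 0.03, -1e-4),
                     label = "dropout")
)
sc  <- simulation_scenario(cl, pi = c(0.5, 0.3, 0.2), sigma_gamma = 1.5,
                           n_patients = 300)
sim <- simulate_cohort(sc, seed = 7)
fit <- fit_mixture(sim$data, G = 3, control = em_control(n_restarts = 2), seed = 1)
fit
```

```
Latent-class hurdle trajectory fit
  G = 3 classes, 300 patients, 27000 observations
  deviance = 86421.3 (AIC 86481.3), converged after 5 outer iterations
Latent-class hurdle trajectory model with 3 classes
sigma_gamma = 1.568 hours; 21 quadrature nodes
pi: 1=0.470, 2=0.340, 3=0.190
```

The fitted proportions recover the generative (.5, .3, .2) mixture to
within sampling error at 300 patients; `sigma_gamma` lands near the
simulated 1.5-hour between-patient spread. The
trajectory table evaluates each class at chosen days — attempt probability,
mean hours and day-to-day SD:

```r
trajectory_table(fit, days = c(1, 45, 90))[, c("class", "day", "attempt_pct",
                                               "mean_hours_r", "sd_hours_r")]
```

```
# A tibble: 9 × 5
  class   day attempt_pct mean_hours_r sd_hours_r
  <int> <dbl>       <dbl>        <dbl>      <dbl>
1     1     1          98          7.3        1
2     1    45          98          7.3        1
3     1    90          98          7.3        1
4     2     1          85          5.9        1.8
5     2    45          74          5.5        1.7
6     2    90          53          5.4        1.9
7     3     1          50          4.1        1.5
8     3    45          23          3.2        1.5
9     3    90          14          3.3        1.4
```

Class 1 attempts therapy 98% of days at a stable 7.3 h; class 2 declines
from 85% to 53% attempts; class 3 collapses to 14% attempts by day 90 —
the three generative archetypes. `augment(fit)` attaches posterior class
probabilities per patient, `autoplot(fit)` draws the three trajectory
panels, and `residual_diagnostics()` + `plot_worm()` give the detrended
Q-Q diagnostic.

The nine-class published preset is available directly:

```r
sim9 <- simulate_cohort(paper_scenario(n_patients = 2000), seed = 11)
trajectory_table(hurdle_mixture(paper_scenario()$classes, paper_scenario()$pi))
```

A command-line front end (`inst/cli/adhere`) wraps the same functions as
`fit`, `simulate`, `evaluate`, `posthoc` and `diagnose` subcommands over
CSV/JSON/YAML files.

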