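---
title: "The spiral changepoint-mixture model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The spiral changepoint-mixture model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiralmix)
```

## The scientific problem

Implicit-theory-of-ability (ITA) research predicts that people who view
ability as fixed ("entity theorists") are more likely than people who view
it as malleable ("incremental theorists") to *spiral*: to show a sustained
performance decline after a setback, rather than recovering. Testing that
prediction requires inference at the level of the individual trajectory,
not just a group mean: the claim is about what each person's trial-by-trial
performance does after failure.

`spiralmix` implements a hierarchical Bayesian analysis of this question
for cohorts of individuals observed over a fixed number of trials
(canonically 28 individuals, split 14/14 by a median split of an 8-item ITA
scale, over 12 trials of a managerial simulation task whose performance
norm is 100).

## The model

**Baseline latent curve model.** Each individual `j` has a straight-line
trajectory

\[
y_{jt} = \alpha_j + \beta_j t + \varepsilon_{jt},\qquad
\varepsilon_{jt}\sim N(0,\sigma^2),
\]

with \(\alpha_j \sim N(\mu_\alpha, \tau_\alpha^2)\) and
\(\beta_j \sim N(\mu_{g(j)}, \tau_\beta^2)\), where \(g(j)\) is the ITA
group. The intercept mean is shared across groups: before any feedback has
been received there is no reason for the groups to differ, so only the
slope mean is group-specific. Random intercept and slope are *independent*
— deliberately not the usual correlated-random-effects mixed model. The
group contrast \(\mu_E - \mu_I\) answers whether entity theorists learn
more slowly on average; `gibbs_lcm()` samples the posterior with fully
conjugate updates, and `fit_lcm_ml()` provides the REML cross-check (same
mean and covariance structure, fitted with `lme4` with the random-effect
correlation suppressed).

**Spiraling extension.** A spiral is a sustained decline: the trajectory
must be monotonically increasing before some cut-point and decreasing after
it. Each individual carries a latent indicator \(S_j\) and, if \(S_j = 1\),
a cut-point \(c_j \in \{1, \dots, T-2\}\) (spirals may not begin in the
last two trials, which would leave too little data to estimate the decline;
\(c_j = 1\) is allowed and makes the whole series post-spiral). Conditional
on \((S_j = 1, c_j)\),

\[
E(y_{jt}) = \begin{cases}
\alpha_{1j} + \beta_{1j} t, & t < c_j\\
\alpha_{1j} + c_j(\beta_{1j} - \beta_{2j}) + \beta_{2j} t, & t \ge c_j
\end{cases}
\]

with \(\beta_{1j}\) drawn from a positive-truncated normal,
\(\beta_{2j}\) from a negative-truncated normal, and the second intercept
pinned by continuity at the cut-point (a point-mass prior: the two
segments meet at \(t = c_j\)). Non-spirallers have \(\beta_{2j} = 0\)
with probability one. The sign constraints are *prior* statements: they
encode the theory's definition of spiraling directly in the model.

**Group propensity.** \(S_j \sim \text{Bernoulli}(\pi_{g(j)})\) with a
logistic parameterization \(\pi_g = \text{logit}^{-1}(\delta_g)\) and
\(\delta \sim N(0, c_\delta I_2)\). The cut-point prior is uniform,
\(\Pr(c_j = t \mid S_j = 1) = 1/(T-2)\). The contrast
\(\pi_E - \pi_I\) answers whether entity theorists are more prone to
spiral.

## Priors

Hyperpriors for the location parameters follow an empirical-Bayes recipe
(`empirical_bayes_priors()`): normal, centered at the average of the
per-individual OLS estimates, with standard deviation equal to half the
range of those estimates. For the spiral model's slope means the recipe is
extended: the pre-spiral slope-mean hyperprior is centered at the mean of
the positive OLS slopes (both group components identically), the
post-spiral one at the negated value, each with sd equal to half the OLS
slope range. This extension is this package's own choice and is isolated in
the prior object so it can be varied in sensitivity analyses.

The remaining constants are weakly informative and data-scaled, again the
package's own defaults rather than canonical values:
\(\sigma^2 \sim IG(2.5, b)\) with \(b\) set so the prior mean equals the
pooled OLS residual variance; each \(\tau^2 \sim IG(2, s)\) with \(s\)
matched to the empirical variance of the corresponding OLS coefficients
(shape 2 keeps the prior mean finite while leaving the variance
uninformative). Degenerate cohorts (zero OLS ranges) get their hyperprior
sds floored at \(10^{-3}\) score units, with a warning.

The default \(c_\delta = 4\) makes the induced prior on each \(\pi_g\)
approximately uniform: the maximal deviation of its CDF from the uniform
CDF is

```{r}
p <- seq(0.001, 0.999, by = 0.0005)
max(abs(pnorm(qlogis(p) / 2) - p))
```

while a strongly equalizing prior, \(c_\delta = 0.01\), places

```{r}
prior_induced_pi(0.01, c(0.45, 0.55))
```

of its mass on \(\pi \in [0.45, 0.55]\) (`prior_induced_pi()` is the
closed form \(\Phi(\text{logit}(b)/\sqrt{c_\delta}) -
\Phi(\text{logit}(a)/\sqrt{c_\delta})\)).

## The sampler

Each individual has \(1 + (T-2)\) candidate models (no spiral, or a spiral
at each admissible cut-point); with 28 individuals the model space has
\(11^{28}\) elements at \(T = 12\), so the sampler averages over models
rather than selecting one.

The central design decision is how to update \((S_j, c_j)\).
`spiralmix` marginalizes the trajectory coefficients *exactly*: for each
candidate state the coefficient integral factorizes into the unconstrained
normal–normal marginal times the ratio of posterior to prior probability
of the sign-constraint region. The posterior constraint term is a
bivariate-normal quadrant probability over \((\beta_1, \beta_2)\) after
the intercept is marginalized; the prior term is a product of univariate
tails (the prior components are independent). The resulting 11-state
discrete conditional is sampled directly in log space. Exactness here is
what makes the update testable: the test suite checks every marginal
against brute-force 2-D quadrature (to \(10^{-4}\) log units) and the
state draws against the enumerated distribution by chi-square.

After a state is drawn, the coefficients are *regenerated* from their
constrained conditional rather than moved by a single Gibbs scan: the
slope pair is drawn by rejection from the unconstrained bivariate-normal
posterior (whose acceptance probability is exactly the quadrant
probability already computed), then the intercept from its conditional
normal. Regenerating independently of the previous coefficient values is
what keeps the composite update exactly invariant; a one-scan Gibbs move
after a marginalized state draw would not be. In the rare case that the
quadrant probability is extremely small, a 20-scan truncated Gibbs
fallback is used from a feasible starting point.

Remaining updates per sweep:

* \(\delta_E, \delta_I\): independent random-walk Metropolis steps on an
  intercept-only logistic posterior (the one-hot group design decouples
  the components); a component whose group is empty is drawn from its
  prior.
* \(\sigma^2\), \(\mu_\alpha\), \(\tau_\alpha^2\): conjugate draws.
* \(\mu_{\beta_1}\) (two components), \(\mu_{\beta_2}\) (two components),
  \(\tau_{\beta_1}^2\), \(\tau_{\beta_2}^2\): random-walk Metropolis (log
  scale for the variances) because the truncated-normal normalizers
  \(\Phi(\mu/\tau)\) break conjugacy; the normalizer is included in the
  target. Only spiralling individuals contribute to the post-spiral
  hyperparameters; with no spirallers those conditionals revert to the
  priors and are drawn directly.

Proposal scales are tuned every 50 iterations during burn-in toward a
~30% acceptance rate and frozen afterwards; post-burn-in acceptance rates
are reported in the chain metadata. Default chain settings are 50,000
iterations, 10,000 burn-in, thinning 5; the examples and tests use much
shorter chains (1,500–8,000 iterations), which this sampler's exact,
well-mixing state update makes adequate at study scale — the problem
sizes used throughout the test suite (J = 28, T = 12; 20 replicate
cohorts for recovery checks; 4-point sensitivity grids; a J = 8 cohort
for the data-free prior-recovery check, where small groups keep the
slope-mean chains' autocorrelation time short) were chosen as the
smallest at which the checks are statistically meaningful.

Numerical floors: variances are floored at \(10^{-8}\); log constraint
probabilities at \(-745\) (the smallest representable double). The
bivariate-normal quadrant probability is computed by a vectorized
Gauss–Legendre scheme (the classical Drezner–Wesolowsky/Genz algorithm,
with the separate expansion for \(|\rho| > 0.925\)), cross-checked against
`mvtnorm` at machine precision in the tests.

**Student-t errors.** `run_spiral_mcmc_t()` replaces the normal errors
with \(t_\nu\) errors through the standard scale-mixture representation
(per-observation inverse-gamma latent variances); every conditional is
adjusted by the latent precision weights. This is a robustness variant:
with large \(\nu\) it reproduces the normal sampler.

## The synthetic-cohort generator

No raw data from the original study are available (only the published
summary table ships with the package, as `example_spiral_table()`), so
`generate_cohort()` simulates the full generative model forward with known
ground truth. Defaults emulate the study conditions: J = 28 in two groups
of 14, T = 12, spiral propensities \(\pi_E = 0.6, \pi_I = 0.15\)
(matching the roughly eight-of-fourteen vs one-or-two-of-fourteen split
the published table implies), intercepts near 102 with sd 5, within-person
noise sd 5, pre-spiral slope means 2.0 (entity) and 1.8 (incremental)
with sd 0.8, post-spiral slope mean −3 with sd 1. These numbers are the
package's calibration, chosen once so that pooled per-group score means
fall near 108–112 and SDs near 12–15 — the descriptive ranges published
for the task being emulated — and they live in `generator_config()`, not
in the code.

What the generator does *not* emulate: the task mechanics behind the
scores (decision strategies, feedback content), serial correlation of
within-person noise beyond the trajectory itself, measurement error in
the ITA classification, and any dependence of the cut-point on the
trajectory so far (the model's uniform cut-point prior is also the
generator's). Passing recovery tests on these cohorts therefore shows the
*inference machinery* works where the model is true; it does not validate
the model against real behavioral data.

## Design choices where the design was open

* **ITA scale aggregation** reports the mean of the eight reversed items:
  published scale statistics on a 1–6 scale (mean ≈ 3.4, sd ≈ 0.7) are
  only consistent with a mean, not a sum; the sum is recorded alongside.
* **Median ties** in the ITA split go to the entity (lower) group and the
  tie count is recorded; any rule here is a convention, not an inference.
* **Missing trials are rejected**, not imputed: the model assumes a
  complete grid.
* **\(\hat c_j\) reporting convention**: the posterior median of
  \(c_j\) conditional on \(S_j = 1\), reported as 0 whenever
  \(\Pr(S_j = 1 \mid Y) \le 0.5\) — this reproduces the zero rows of the
  published summary table.
* **The learning-rate contrast under the spiral model** is computed on
  the *pre-spiral* slope means \(\mu_{E1} - \mu_{I1}\): that is the
  quantity the baseline model's slope contrast becomes once the
  post-setback decline is modeled separately.
* **Sensitivity sweeps refit per grid point** with the same seed policy
  (simple and honest) rather than importance-reweighting a single chain.
* **Cut-point at 1 is admissible**: the published table itself contains
  an individual whose spiral is estimated to begin at the first trial.

## Known limitations

* The sampler is exact but single-chain; convergence assessment beyond
  acceptance rates and the built-in prior-recovery checks (effective
  sample sizes, multiple chains) is left to the user via the draws table.
* One changepoint per individual, with an increase-then-decrease shape;
  recovery after a spiral, multiple setbacks, or nonlinear segments are
  out of scope.
* No covariance between random intercepts and slopes, by model
  definition.
* With very small groups the \(\mu_{\beta_2}\) and \(\tau_{\beta_2}^2\)
  conditionals lean heavily on their (package-default) hyperpriors;
  sensitivity analysis over those constants is recommended, and the prior
  object makes them explicit for exactly that reason.
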