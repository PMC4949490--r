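# Synthetic cohorts drawn from the full spiral generative model, with known
# ground truth. Stands in for the original (undeposited) study data.

#' Generator configuration
#'
#' Defaults emulate the study design this model was built for: J = 28
#' individuals in two ITA groups of 14, T = 12 trials, performance scores on
#' a scale whose norm is 100. Group-level parameters are in score units
#' (intercepts, noise) and score-per-trial units (slopes). Spiral
#' propensities default to a clear entity/incremental contrast
#' (`pi = c(entity = 0.6, incremental = 0.15)`). Slope and noise scales are
#' calibrated so pooled per-group score means sit near 108-112 with SDs near
#' 12-15, matching the published descriptives of the task the generator
#' emulates.
#'
#' @param J Number of individuals.
#' @param T Number of trials (>= 4).
#' @param n_entity Number of entity-group individuals (rest incremental).
#' @param mu_alpha,tau_alpha Mean and SD of individual intercepts
#'   (score units).
#' @param mu_beta1 Named length-2 vector: pre-spiral slope-mean per group
#'   before positive truncation (score/trial).
#' @param tau_beta1 SD of the pre-spiral slope distribution.
#' @param mu_beta2 Named length-2 vector: post-spiral slope-mean per group
#'   before negative truncation.
#' @param tau_beta2 SD of the post-spiral slope distribution.
#' @param sigma Within-person noise SD (score units).
#' @param pi Named length-2 vector of spiral probabilities per group, or
#'   `NULL` to derive from `delta`.
#' @param delta Optional named length-2 vector of logistic coefficients;
#'   `pi = plogis(delta)`.
#' @param error Error family: `"normal"` or `"t"`.
#' @param nu Degrees of freedom for `error = "t"` (> 2).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(J = 28, T = 12, n_entity = J / 2,
                             mu_alpha = 102, tau_alpha = 5,
                             mu_beta1 = c(entity = 2.0, incremental = 1.8),
                             tau_beta1 = 0.8,
                             mu_beta2 = c(entity = -3, incremental = -3),
                             tau_beta2 = 1,
                             sigma = 5,
                             pi = c(entity = 0.6, incremental = 0.15),
                             delta = NULL,
                             error = c("normal", "t"), nu = 5) {
  error <- match.arg(error)
  if (is.null(pi)) {
    stopifnot(!is.null(delta), length(delta) == 2)
    pi <- stats::plogis(delta)
    names(pi) <- c("entity", "incremental")
  }
  stopifnot(T >= 4, J >= 1, n_entity >= 0, n_entity <= J,
            tau_alpha > 0, tau_beta1 > 0, tau_beta2 > 0, sigma >= 0,
            all(pi >= 0), all(pi <= 1),
            all(is.finite(c(mu_alpha, mu_beta1, mu_beta2))))
  if (error == "t") stopifnot(nu > 2)
  cfg <- list(J = J, T = as.integer(T), n_entity = n_entity,
              mu_alpha = mu_alpha, tau_alpha = tau_alpha,
              mu_beta1 = mu_beta1, tau_beta1 = tau_beta1,
              mu_beta2 = mu_beta2, tau_beta2 = tau_beta2,
              sigma = sigma, pi = pi, error = error, nu = nu)
  class(cfg) <- "generator_config"
  cfg
}

#' Noiseless piecewise-linear trajectory mean
#'
#' `alpha1 + beta1 * t` before the cut-point and
#' `alpha1 + c (beta1 - beta2) + beta2 * t` from trial `c` on; the two
#' segments agree at `t = c`, so the mean is continuous there.
#'
#' @param t Trial vector.
#' @param alpha1,beta1,beta2 Coefficients; `beta2` ignored when `S = 0`.
#' @param S Spiral indicator (0/1).
#' @param cut Cut-point (used when `S = 1`).
#' @return Numeric vector of means.
#' @export
trajectory_mean <- function(t, alpha1, beta1, beta2, S, cut) {
  if (S == 0) return(alpha1 + beta1 * t)
  ifelse(t < cut,
         alpha1 + beta1 * t,
         alpha1 + cut * (beta1 - beta2) + beta2 * t)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Forward simulation of the full hierarchical spiral model: per individual,
#' a spiral indicator `S_j ~ Bernoulli(pi_group)`, a cut-point `c_j` uniform
#' on `{1, ..., T-2}` given `S_j = 1` (a spiral may not begin in the last
#' two trials; `c_j = 1` is allowed and makes the whole series post-spiral),
#' an intercept `alpha_1j ~ N(mu_alpha, tau_alpha^2)`, a pre-spiral slope
#' from the positive-truncated normal, and a post-spiral slope from the
#' negative-truncated normal for spirallers or exactly 0 (the point-mass
#' component) otherwise. Scores are the piecewise-linear mean plus noise;
#' `error = "t"` uses the scale-mixture representation (inverse-gamma latent
#' variances scaling normal draws).
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; the draw is fully reproducible from it.
#' @return A list with `cohort` (validated cohort tibble) and `truth`
#'   (tibble: `individual`, `group`, `S`, `cut`, `alpha1`, `beta1`, `beta2`).
#' @export
generate_cohort <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  J <- config$J; T <- config$T
  ids <- sprintf("%02d", seq_len(J))
  group <- rep(c("entity", "incremental"),
               c(config$n_entity, J - config$n_entity))
  pi_j <- config$pi[group]
  S <- stats::rbinom(J, 1, pi_j)
  cut <- ifelse(S == 1, sample.int(T - 2, J, replace = TRUE), NA_integer_)
  alpha1 <- stats::rnorm(J, config$mu_alpha, config$tau_alpha)
  beta1 <- truncnorm::rtruncnorm(J, a = 0, b = Inf,
                                 mean = config$mu_beta1[group],
                                 sd = config$tau_beta1)
  beta2 <- ifelse(
    S == 1,
    truncnorm::rtruncnorm(J, a = -Inf, b = 0,
                          mean = config$mu_beta2[group],
                          sd = config$tau_beta2),
    0
  )
  rows <- purrr::map(seq_len(J), function(j) {
    t <- seq_len(T)
    mu <- trajectory_mean(t, alpha1[j], beta1[j], beta2[j], S[j], cut[j])
    eps <- stats::rnorm(T, 0, config$sigma)
    if (config$error == "t") {
      # scale mixture: lambda ~ IG(nu/2, nu/2) => sqrt(lambda)*z is t_nu
      lambda <- 1 / stats::rgamma(T, config$nu / 2, rate = config$nu / 2)
      eps <- eps * sqrt(lambda)
    }
    tibble::tibble(individual = ids[j], group = group[j], trial = t,
                   score = mu + eps)
  })
  cohort <- as_cohort(dplyr::bind_rows(rows))
  truth <- tibble::tibble(individual = ids, group = group, S = S,
                          cut = ifelse(S == 1, cut, NA_integer_),
                          alpha1 = alpha1, beta1 = beta1, beta2 = beta2)
  list(cohort = cohort, truth = truth, config = config, seed = seed)
}

#' Study-scale synthetic fixture
#'
#' A 28-individual, 12-trial cohort (two groups of 14) drawn from the
#' default generator configuration. Byte-identical when regenerated with the
#' same seed.
#'
#' @param seed Integer seed.
#' @return As [generate_cohort()].
#' @export
study_like_fixture <- function(seed = 1) {
  generate_cohort(generator_config(), seed = seed)
}
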