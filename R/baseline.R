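# The no-spiral latent curve model: per-individual straight-line
# trajectories with a shared intercept mean and group-specific slope means,
# fitted by conjugate Gibbs sampling and, as a frequentist cross-check, by
# REML. Random intercept and random slope are independent by construction
# (no covariance term).

#' Gibbs sampler for the baseline latent curve model
#'
#' `y_jt = alpha_j + beta_j t + eps`, with `alpha_j ~ N(mu_alpha,
#' tau_alpha^2)`, `beta_j ~ N(mu_group, tau_beta^2)` (group-specific slope
#' mean, shared slope variance) and `sigma^2 ~ IG(a, b)`. All full
#' conditionals are conjugate.
#'
#' @param cohort A cohort tibble.
#' @param priors A `spiral_priors` object; uses `mu_alpha`, `mu_beta`,
#'   `sigma2`, `tau_alpha2` and `tau_beta2_lcm`.
#' @param n_iter,burn_in,thin Chain control.
#' @param seed Integer seed (required).
#' @param prior_only Disable the likelihood (prior-recovery checks).
#' @return Tibble of retained draws, class `lcm_draws`: columns `mu_alpha`,
#'   `mu_E`, `mu_I`, `tau_alpha2`, `tau_beta2`, `sigma2` and per-individual
#'   `alpha_<id>`, `beta_<id>`; chain metadata in attributes.
#' @export
gibbs_lcm <- function(cohort, priors, n_iter = 20000, burn_in = 5000,
                      thin = 1, seed, prior_only = FALSE) {
  stopifnot(inherits(priors, "spiral_priors"), n_iter > burn_in)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  d <- cohort_dims(cohort)
  y <- cohort_matrix(cohort)
  J <- d$J; T <- d$T
  group_is_entity <- unname(d$group) == "entity"
  t <- seq_len(T)
  st2 <- sum(t^2)
  yt <- drop(y %*% t)          # sum_t t*y_jt
  ysum <- rowSums(y)
  kap <- if (prior_only) 0 else 1

  mu_alpha <- priors$mu_alpha[["center"]]
  mu_E <- mu_I <- priors$mu_beta[["center"]]
  tau_a2 <- max(priors$tau_alpha2[["scale"]], .VAR_FLOOR)
  tau_b2 <- max(priors$tau_beta2_lcm[["scale"]], .VAR_FLOOR)
  sigma2 <- max(mean(per_individual_ols(cohort)$resid_var), .VAR_FLOOR)
  alpha <- rep(mu_alpha, J)
  beta <- rep(mu_E, J)

  keep_iters <- seq(burn_in + thin, n_iter, by = thin)
  n_keep <- length(keep_iters)
  cols <- c("mu_alpha", "mu_E", "mu_I", "tau_alpha2", "tau_beta2", "sigma2",
            paste0("alpha_", d$ids), paste0("beta_", d$ids))
  draws <- matrix(NA_real_, n_keep, length(cols),
                  dimnames = list(NULL, cols))
  row <- 0L

  for (iter in seq_len(n_iter)) {
    mu_g <- ifelse(group_is_entity, mu_E, mu_I)
    # alpha_j | .
    prec_a <- kap * T / sigma2 + 1 / tau_a2
    mean_a <- (kap * (ysum - beta * sum(t)) / sigma2 + mu_alpha / tau_a2) /
      prec_a
    alpha <- stats::rnorm(J, mean_a, sqrt(1 / prec_a))
    # beta_j | .
    prec_b <- kap * st2 / sigma2 + 1 / tau_b2
    mean_b <- (kap * (yt - alpha * sum(t)) / sigma2 + mu_g / tau_b2) / prec_b
    beta <- stats::rnorm(J, mean_b, sqrt(1 / prec_b))
    # mu_alpha | .
    h <- priors$mu_alpha
    prec <- 1 / h[["sd"]]^2 + J / tau_a2
    mu_alpha <- stats::rnorm(1, (h[["center"]] / h[["sd"]]^2 +
                                   sum(alpha) / tau_a2) / prec,
                             sqrt(1 / prec))
    # mu_E, mu_I | .
    hb <- priors$mu_beta
    for (g in c(TRUE, FALSE)) {
      in_g <- group_is_entity == g
      n_g <- sum(in_g)
      prec <- 1 / hb[["sd"]]^2 + n_g / tau_b2
      m <- (hb[["center"]] / hb[["sd"]]^2 + sum(beta[in_g]) / tau_b2) / prec
      val <- stats::rnorm(1, m, sqrt(1 / prec))
      if (g) mu_E <- val else mu_I <- val
    }
    # variances
    tau_a2 <- max(.rinvgamma(1, priors$tau_alpha2[["shape"]] + J / 2,
                             priors$tau_alpha2[["scale"]] +
                               sum((alpha - mu_alpha)^2) / 2), .VAR_FLOOR)
    mu_g <- ifelse(group_is_entity, mu_E, mu_I)
    tau_b2 <- max(.rinvgamma(1, priors$tau_beta2_lcm[["shape"]] + J / 2,
                             priors$tau_beta2_lcm[["scale"]] +
                               sum((beta - mu_g)^2) / 2), .VAR_FLOOR)
    if (prior_only) {
      sigma2 <- max(.rinvgamma(1, priors$sigma2[["shape"]],
                               priors$sigma2[["scale"]]), .VAR_FLOOR)
    } else {
      resid <- y - (alpha + outer(beta, t))
      sigma2 <- max(.rinvgamma(1, priors$sigma2[["shape"]] + J * T / 2,
                               priors$sigma2[["scale"]] +
                                 sum(resid^2) / 2), .VAR_FLOOR)
    }

    if (iter > burn_in && (iter - burn_in) %% thin == 0) {
      row <- row + 1L
      draws[row, ] <- c(mu_alpha, mu_E, mu_I, tau_a2, tau_b2, sigma2,
                        alpha, beta)
    }
  }
  out <- tibble::as_tibble(as.data.frame(draws))
  attr(out, "ids") <- d$ids
  attr(out, "labels") <- d$group
  attr(out, "seed") <- seed
  attr(out, "n_iter") <- n_iter
  attr(out, "burn_in") <- burn_in
  attr(out, "thin") <- thin
  attr(out, "prior_only") <- prior_only
  class(out) <- c("lcm_draws", class(out))
  out
}

#' REML fit of the baseline latent curve model
#'
#' Restricted maximum likelihood fit of the linear mixed model with
#' independent random intercepts and random slopes and group-specific fixed
#' slope means, via `lme4::lmer` with the covariance between random effects
#' suppressed. Serves as the frequentist comparison for [gibbs_lcm()].
#'
#' @param cohort A cohort tibble.
#' @param per_group_intercept If `TRUE`, estimate a separate fixed intercept
#'   per group; the default (`FALSE`) shares one intercept, matching the
#'   Bayesian model.
#' @return An object of class `lcm_ml`: list with `estimates` (tibble
#'   `term`, `estimate`, `se`), `varcomp` (tibble `component`, `variance`)
#'   and the underlying `lme4` fit.
#' @export
fit_lcm_ml <- function(cohort, per_group_intercept = FALSE) {
  dat <- tibble::as_tibble(cohort)
  dat$group <- factor(dat$group, levels = .group_levels)
  form <- if (per_group_intercept) {
    score ~ 0 + group + trial:group + (1 | individual) +
      (0 + trial | individual)
  } else {
    score ~ 1 + trial:group + (1 | individual) + (0 + trial | individual)
  }
  fit <- lme4::lmer(form, data = dat, REML = TRUE)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  term_map <- c("(Intercept)" = "mu_alpha",
                "groupentity" = "mu_alpha_entity",
                "groupincremental" = "mu_alpha_incremental",
                "groupentity:trial" = "mu_E",
                "trial:groupentity" = "mu_E",
                "groupincremental:trial" = "mu_I",
                "trial:groupincremental" = "mu_I")
  terms <- unname(term_map[names(fe)])
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- ifelse(vc$grp == "Residual", "sigma2",
                 ifelse(vc$var1 == "(Intercept)", "tau_alpha2", "tau_beta2"))
  out <- list(
    estimates = tibble::tibble(term = terms, estimate = unname(fe),
                               se = unname(se)),
    varcomp = tibble::tibble(component = comp, variance = vc$vcov),
    fit = fit
  )
  class(out) <- "lcm_ml"
  out
}

#' @export
print.lcm_ml <- function(x, ...) {
  cat("Baseline latent curve model (REML)\n")
  print(x$estimates)
  print(x$varcomp)
  invisible(x)
}

#' Posterior contrast of the group slope means
#'
#' Draw-wise difference of the entity and incremental slope means
#' (`mu_E - mu_I` for a baseline fit; pre-spiral slope means
#' `mu_beta1_entity - mu_beta1_incremental` for a spiral fit, i.e. the
#' model's learning-rate contrast), the fraction of draws below zero, and
#' histogram bin counts.
#'
#' @param draws An `lcm_draws` or `spiral_draws` tibble.
#' @param bins Number of histogram bins.
#' @return List of class `slope_contrast`: `diffs` (numeric vector),
#'   `frac_below_zero`, `hist` (tibble `mid`, `count`).
#' @export
slope_contrast <- function(draws, bins = 40) {
  if (inherits(draws, "spiral_draws")) {
    diffs <- draws$mu_beta1_entity - draws$mu_beta1_incremental
  } else {
    diffs <- draws$mu_E - draws$mu_I
  }
  h <- graphics::hist(diffs, breaks = bins, plot = FALSE)
  out <- list(diffs = diffs,
              frac_below_zero = mean(diffs < 0),
              hist = tibble::tibble(mid = h$mids, count = h$counts))
  class(out) <- "slope_contrast"
  out
}

#' Batch-means Monte-Carlo standard error of a chain mean
#'
#' @param x Numeric vector of (possibly autocorrelated) MCMC draws.
#' @param n_batches Number of batches.
#' @return Scalar standard error of `mean(x)`.
#' @export
mcse_mean <- function(x, n_batches = 30) {
  n <- length(x)
  b <- max(2, floor(n / n_batches))
  nb <- floor(n / b)
  bm <- vapply(seq_len(nb), function(i) mean(x[((i - 1) * b + 1):(i * b)]),
               numeric(1))
  stats::sd(bm) / sqrt(nb)
}
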