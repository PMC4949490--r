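# Data-augmentation MCMC for the spiral changepoint-mixture model.
#
# Each sweep updates, in order: (S_j, c_j) for every individual from the
# exact coefficient-marginalized 11-state conditional (batched across
# individuals and cut-points); the trajectory coefficients, regenerated
# exactly from their constrained conditional given the new state; the
# logistic propensity coefficients delta by random-walk Metropolis; and the
# group-level hyperparameters (conjugate updates where conjugacy holds,
# Metropolis on the truncated-normal means/variances whose normalizers
# break it). Proposal scales are tuned during burn-in toward ~30%
# acceptance and then frozen.

.VAR_FLOOR <- 1e-8

# --- design precomputation -------------------------------------------------

.design_stats <- function(T) {
  t <- seq_len(T)
  C <- T - 2
  Mmin <- vapply(seq_len(C), function(cc) pmin(t, cc), numeric(T))
  Mpos <- vapply(seq_len(C), function(cc) pmax(t - cc, 0), numeric(T))
  list(T = T, C = C, t = t, Mmin = Mmin, Mpos = Mpos,
       Mmin2 = Mmin^2, Mpos2 = Mpos^2, Mcross = Mmin * Mpos)
}

# weighted cross-products of the designs with the data, for all individuals
# (rows of y) and all cut-points at once
.cross_stats <- function(y, w, ds) {
  wy <- w * y
  list(
    s11 = rowSums(w),                 # J
    s12 = w %*% ds$Mmin,              # J x C
    s13 = w %*% ds$Mpos,
    s22 = w %*% ds$Mmin2,
    s23 = w %*% ds$Mcross,
    s33 = w %*% ds$Mpos2,
    u1 = rowSums(wy),
    u2 = wy %*% ds$Mmin,
    u3 = wy %*% ds$Mpos,
    s12n = drop(w %*% ds$t),          # null (straight-line) model
    s22n = drop(w %*% ds$t^2),
    u2n = drop(wy %*% ds$t),
    yty = rowSums(wy * y),
    sumlogw = rowSums(log(w))
  )
}

# --- batched state update --------------------------------------------------

# Computes the 11-state log masses for every individual and samples a state
# per individual; also returns the posterior moments needed to regenerate
# coefficients for the selected states.
.state_update <- function(cs, ds, hy, group_is_entity, pi_j, sigma2,
                          prior_only = FALSE) {
  J <- length(cs$u1)
  C <- ds$C
  T <- ds$T
  va <- hy$tau_alpha2; v1 <- hy$tau_beta1_sq; v2 <- hy$tau_beta2_sq
  a0 <- hy$mu_alpha
  b1g <- ifelse(group_is_entity, hy$mu_beta1[["entity"]],
                hy$mu_beta1[["incremental"]])
  b2g <- ifelse(group_is_entity, hy$mu_beta2[["entity"]],
                hy$mu_beta2[["incremental"]])
  kap <- if (prior_only) 0 else 1 / sigma2

  # spiral models: 3x3 posterior, batched over J x C
  a11 <- cs$s11 * kap + 1 / va            # J (recycles down columns)
  a12 <- cs$s12 * kap
  a13 <- cs$s13 * kap
  a22 <- cs$s22 * kap + 1 / v1
  a23 <- cs$s23 * kap
  a33 <- cs$s33 * kap + 1 / v2
  det3 <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
    a13 * (a12 * a23 - a22 * a13)
  i11 <- (a22 * a33 - a23^2) / det3
  i12 <- (a13 * a23 - a12 * a33) / det3
  i13 <- (a12 * a23 - a13 * a22) / det3
  i22 <- (a11 * a33 - a13^2) / det3
  i23 <- (a12 * a13 - a11 * a23) / det3
  i33 <- (a11 * a22 - a12^2) / det3
  bb1 <- cs$u1 * kap + a0 / va
  bb2 <- cs$u2 * kap + b1g / v1
  bb3 <- cs$u3 * kap + b2g / v2
  mn1 <- i11 * bb1 + i12 * bb2 + i13 * bb3
  mn2 <- i12 * bb1 + i22 * bb2 + i23 * bb3
  mn3 <- i13 * bb1 + i23 * bb2 + i33 * bb3
  s2 <- sqrt(i22); s3 <- sqrt(i33)
  p_post <- matrix(pbvn_quadrant(mn2, mn3, s2, s3, i23 / (s2 * s3)), J, C)
  lp_b1 <- stats::pnorm(b1g / sqrt(v1), log.p = TRUE)
  lp_b2 <- stats::pnorm(-b2g / sqrt(v2), log.p = TRUE)
  if (prior_only) {
    log_mass_c <- matrix(rep(.log_floor(pi_j) - log(C), C), J, C)
  } else {
    m0Dm0 <- a0^2 / va + b1g^2 / v1 + b2g^2 / v2
    pm_unc <- -T / 2 * log(2 * pi) -
      (T * log(sigma2) - cs$sumlogw) / 2 -
      log(va * v1 * v2) / 2 - log(det3) / 2 -
      (cs$yty / sigma2 + m0Dm0 - (bb1 * mn1 + bb2 * mn2 + bb3 * mn3)) / 2
    log_mass_c <- .log_floor(pi_j) - log(C) + pm_unc +
      .log_floor(p_post) - (lp_b1 + lp_b2)
  }

  # null model: 2x2 posterior, batched over J
  a11n <- cs$s11 * kap + 1 / va
  a12n <- cs$s12n * kap
  a22n <- cs$s22n * kap + 1 / v1
  detn <- a11n * a22n - a12n^2
  i11n <- a22n / detn; i12n <- -a12n / detn; i22n <- a11n / detn
  bb1n <- cs$u1 * kap + a0 / va
  bb2n <- cs$u2n * kap + b1g / v1
  mn1n <- i11n * bb1n + i12n * bb2n
  mn2n <- i12n * bb1n + i22n * bb2n
  p_post0 <- stats::pnorm(mn2n / sqrt(i22n))
  if (prior_only) {
    log_mass_0 <- .log_floor(1 - pi_j)
  } else {
    pm_unc0 <- -T / 2 * log(2 * pi) -
      (T * log(sigma2) - cs$sumlogw) / 2 -
      log(va * v1) / 2 - log(detn) / 2 -
      (cs$yty / sigma2 + a0^2 / va + b1g^2 / v1 -
         (bb1n * mn1n + bb2n * mn2n)) / 2
    log_mass_0 <- .log_floor(1 - pi_j) + pm_unc0 +
      .log_floor(p_post0) - lp_b1
  }

  logW <- cbind(log_mass_0, log_mass_c)      # J x (C + 1)
  if (any(!is.finite(rowSums(exp(logW - apply(logW, 1, max)))))) {
    stop("non-finite spiral-state masses; chain diverged", call. = FALSE)
  }
  gumbel <- -log(-log(matrix(stats::runif(J * (C + 1)), J, C + 1)))
  pick <- max.col(logW + gumbel, ties.method = "first")
  S <- as.integer(pick > 1)
  cut <- ifelse(S == 1, pick - 1L, NA_integer_)

  list(S = S, cut = cut, logW = logW,
       spiral = list(mn1 = mn1, mn2 = mn2, mn3 = mn3, i11 = i11, i12 = i12,
                     i13 = i13, i22 = i22, i23 = i23, i33 = i33),
       null = list(mn1 = mn1n, mn2 = mn2n, i11 = i11n, i12 = i12n,
                   i22 = i22n))
}

# Exact draw of (beta1, beta2) from a bivariate normal restricted to the
# quadrant {b1 > 0, b2 < 0}: vectorized rejection from the unconstrained
# bivariate (acceptance probability = the quadrant probability), with a
# truncated-Gibbs fallback for the rare deep-constraint cases.
.rquadrant <- function(mn2, mn3, i22, i23, i33, max_rounds = 80) {
  m <- length(mn2)
  b1 <- b2 <- numeric(m)
  todo <- seq_len(m)
  cv <- pmax(i33 - i23^2 / i22, .VAR_FLOOR)
  for (r in seq_len(max_rounds)) {
    k <- length(todo)
    z1 <- stats::rnorm(k, mn2[todo], sqrt(i22[todo]))
    z2 <- stats::rnorm(k, mn3[todo] + i23[todo] / i22[todo] *
                         (z1 - mn2[todo]), sqrt(cv[todo]))
    ok <- z1 > 0 & z2 < 0
    b1[todo[ok]] <- z1[ok]
    b2[todo[ok]] <- z2[ok]
    todo <- todo[!ok]
    if (length(todo) == 0) break
  }
  if (length(todo) > 0) {
    cv1 <- pmax(i22 - i23^2 / i33, .VAR_FLOOR)
    for (j in todo) {
      bb2 <- if (mn3[j] < 0) mn3[j] else -0.5 * sqrt(i33[j])
      bb1 <- NA_real_
      for (s in 1:20) {
        bb1 <- truncnorm::rtruncnorm(
          1, a = 0, b = Inf,
          mean = mn2[j] + i23[j] / i33[j] * (bb2 - mn3[j]),
          sd = sqrt(cv1[j]))
        bb2 <- truncnorm::rtruncnorm(
          1, a = -Inf, b = 0,
          mean = mn3[j] + i23[j] / i22[j] * (bb1 - mn2[j]),
          sd = sqrt(cv[j]))
      }
      b1[j] <- bb1; b2[j] <- bb2
    }
  }
  list(b1 = b1, b2 = b2)
}

# regenerate all coefficients from p(theta | S, c, y, hypers)
.regen_coefficients <- function(st) {
  J <- length(st$S)
  alpha1 <- beta1 <- beta2 <- numeric(J)
  sp <- which(st$S == 1)
  ns <- which(st$S == 0)
  if (length(sp) > 0) {
    idx <- cbind(sp, st$cut[sp])
    g <- st$spiral
    mn2 <- g$mn2[idx]; mn3 <- g$mn3[idx]
    i22 <- g$i22[idx]; i23 <- g$i23[idx]; i33 <- g$i33[idx]
    bq <- .rquadrant(mn2, mn3, i22, i23, i33)
    beta1[sp] <- bq$b1
    beta2[sp] <- bq$b2
    # alpha1 | (beta1, beta2): condition the 3x3 normal on the slopes
    detb <- i22 * i33 - i23^2
    w1 <- (g$i12[idx] * i33 - g$i13[idx] * i23) / detb
    w2 <- (g$i13[idx] * i22 - g$i12[idx] * i23) / detb
    cm <- g$mn1[idx] + w1 * (bq$b1 - mn2) + w2 * (bq$b2 - mn3)
    cvar <- pmax(g$i11[idx] - (w1 * g$i12[idx] + w2 * g$i13[idx]),
                 .VAR_FLOOR)
    alpha1[sp] <- stats::rnorm(length(sp), cm, sqrt(cvar))
  }
  if (length(ns) > 0) {
    n0 <- st$null
    b1 <- truncnorm::rtruncnorm(length(ns), a = 0, b = Inf,
                                mean = n0$mn2[ns], sd = sqrt(n0$i22[ns]))
    beta1[ns] <- b1
    cm <- n0$mn1[ns] + n0$i12[ns] / n0$i22[ns] * (b1 - n0$mn2[ns])
    cvar <- pmax(n0$i11[ns] - n0$i12[ns]^2 / n0$i22[ns], .VAR_FLOOR)
    alpha1[ns] <- stats::rnorm(length(ns), cm, sqrt(cvar))
    beta2[ns] <- 0
  }
  tibble::tibble(alpha1 = alpha1, beta1 = beta1, beta2 = beta2)
}

#' Draw trajectory coefficients from their constrained conditional
#'
#' Given a spiral state, draws `(alpha1, beta1, beta2)` from their joint
#' full conditional: the sign-constrained normal posterior. The slope pair
#' is drawn exactly (rejection from the unconstrained bivariate-normal
#' posterior, whose acceptance probability is the constraint-region
#' probability), then the intercept from its conditional normal. Under the
#' no-spiral state `beta2` is exactly 0 (point-mass prior) and only
#' `beta1 > 0` is enforced.
#'
#' @inheritParams log_marginal
#' @param n Number of draws.
#' @return Tibble with `n` rows: `alpha1`, `beta1`, `beta2`.
#' @export
sample_coefficients <- function(y, state, hypers, sigma2, n = 1,
                                weights = NULL) {
  T <- length(y)
  if (is.null(weights)) weights <- rep(1, T)
  spiral <- state$S == 1
  if (spiral) {
    X <- piecewise_design(state$cut, T)
    m0 <- c(hypers$mu_alpha, hypers$mu_beta1, hypers$mu_beta2)
    v0 <- c(hypers$tau_alpha2, hypers$tau_beta1_sq, hypers$tau_beta2_sq)
  } else {
    X <- cbind(1, seq_len(T))
    m0 <- c(hypers$mu_alpha, hypers$mu_beta1)
    v0 <- c(hypers$tau_alpha2, hypers$tau_beta1_sq)
  }
  A <- crossprod(X * weights, X) / sigma2 + diag(1 / v0, length(v0))
  Vn <- solve(A)
  mn <- drop(Vn %*% (crossprod(X * weights, y) / sigma2 + m0 / v0))
  if (spiral) {
    bq <- .rquadrant(rep(mn[2], n), rep(mn[3], n),
                     rep(Vn[2, 2], n), rep(Vn[2, 3], n), rep(Vn[3, 3], n))
    Sbb <- Vn[2:3, 2:3]
    w <- solve(Sbb, Vn[2:3, 1])
    cvar <- pmax(Vn[1, 1] - sum(w * Vn[2:3, 1]), .VAR_FLOOR)
    cm <- mn[1] + w[1] * (bq$b1 - mn[2]) + w[2] * (bq$b2 - mn[3])
    tibble::tibble(alpha1 = stats::rnorm(n, cm, sqrt(cvar)),
                   beta1 = bq$b1, beta2 = bq$b2)
  } else {
    b1 <- truncnorm::rtruncnorm(n, a = 0, b = Inf, mean = mn[2],
                                sd = sqrt(Vn[2, 2]))
    cm <- mn[1] + Vn[1, 2] / Vn[2, 2] * (b1 - mn[2])
    cvar <- pmax(Vn[1, 1] - Vn[1, 2]^2 / Vn[2, 2], .VAR_FLOOR)
    tibble::tibble(alpha1 = stats::rnorm(n, cm, sqrt(cvar)),
                   beta1 = b1, beta2 = 0)
  }
}

# --- Metropolis pieces -----------------------------------------------------

.ldinvgamma <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

.rinvgamma <- function(n, shape, scale) {
  1 / stats::rgamma(n, shape = shape, rate = scale)
}

.mh_step <- function(cur, logpost, sd) {
  prop <- cur + stats::rnorm(1, 0, sd)
  lr <- logpost(prop) - logpost(cur)
  if (is.finite(lr) && log(stats::runif(1)) < lr) {
    list(value = prop, accepted = TRUE)
  } else {
    list(value = cur, accepted = FALSE)
  }
}

#' One Metropolis update of the logistic spiral-propensity coefficients
#'
#' The conditional of `delta = (delta_E, delta_I)` given the spiral
#' indicators is an intercept-only logistic regression per group (the
#' one-hot design makes the components independent) with a `N(0, c_delta)`
#' prior. Each component takes one random-walk Metropolis step; a component
#' whose group has no members is drawn directly from its prior.
#'
#' @param delta Named numeric vector `c(entity = , incremental = )`.
#' @param S Integer 0/1 vector of spiral indicators.
#' @param group Character vector of group labels, parallel to `S`.
#' @param c_delta Prior variance.
#' @param prop_sd Proposal SD (scalar or named length-2).
#' @return List with `delta` (updated vector) and `accepted` (named logical;
#'   `NA` for prior-drawn components).
#' @export
update_delta <- function(delta, S, group, c_delta, prop_sd = 0.5) {
  prop_sd <- rep_len(prop_sd, 2)
  accepted <- c(entity = NA, incremental = NA)
  for (i in seq_along(.group_levels)) {
    g <- .group_levels[i]
    in_g <- group == g
    n_g <- sum(in_g)
    if (n_g == 0) {
      delta[[g]] <- stats::rnorm(1, 0, sqrt(c_delta))
      next
    }
    k_g <- sum(S[in_g])
    lp <- function(d) {
      k_g * d - n_g * log1p(exp(d)) - d^2 / (2 * c_delta)
    }
    step <- .mh_step(delta[[g]], lp, prop_sd[i])
    delta[[g]] <- step$value
    accepted[[g]] <- step$accepted
  }
  list(delta = delta, accepted = accepted)
}

#' One sweep of the group-level hyperparameter updates
#'
#' Conjugate draws for the observation variance (inverse gamma), the
#' intercept mean (normal) and intercept variance (inverse gamma);
#' random-walk Metropolis for the truncated-normal slope means and (on the
#' log scale) slope variances, whose truncation normalizers
#' `Phi(mu/tau)` enter the target. Only spiralling individuals contribute
#' to the post-spiral slope hyperparameters; with no spirallers those
#' conditionals equal their priors and are drawn directly.
#'
#' @param coefs Tibble with columns `alpha1`, `beta1`, `beta2`.
#' @param states Tibble with columns `S`, `cut`.
#' @param group Character vector of group labels.
#' @param priors A `spiral_priors` object.
#' @param current Named list of current values: `mu_alpha`, `tau_alpha2`,
#'   `sigma2`, `mu_beta1`, `mu_beta2` (named length-2), `tau_beta1_sq`,
#'   `tau_beta2_sq`.
#' @param resid_ss Weighted residual sum of squares under the current
#'   trajectory means (0 for a prior-only run).
#' @param n_obs Number of observations behind `resid_ss`.
#' @param prop_sd Named numeric vector of proposal SDs (`mu_b1_entity`,
#'   `mu_b1_incremental`, `mu_b2_entity`, `mu_b2_incremental`,
#'   `log_tau_b1`, `log_tau_b2`).
#' @return List `current` (updated), `accepted` (named logical).
#' @export
update_hypers <- function(coefs, states, group, priors, current,
                          resid_ss = 0, n_obs = 0,
                          prop_sd = c(mu_b1_entity = 0.3,
                                      mu_b1_incremental = 0.3,
                                      mu_b2_entity = 0.3,
                                      mu_b2_incremental = 0.3,
                                      log_tau_b1 = 0.4, log_tau_b2 = 0.4)) {
  J <- nrow(coefs)
  acc <- c(mu_b1_entity = NA, mu_b1_incremental = NA,
           mu_b2_entity = NA, mu_b2_incremental = NA,
           log_tau_b1 = NA, log_tau_b2 = NA)

  # sigma^2 (conjugate)
  current$sigma2 <- max(.rinvgamma(1, priors$sigma2[["shape"]] + n_obs / 2,
                                   priors$sigma2[["scale"]] + resid_ss / 2),
                        .VAR_FLOOR)

  # mu_alpha (conjugate normal-normal)
  h <- priors$mu_alpha
  prec <- 1 / h[["sd"]]^2 + J / current$tau_alpha2
  mean_ <- (h[["center"]] / h[["sd"]]^2 +
              sum(coefs$alpha1) / current$tau_alpha2) / prec
  current$mu_alpha <- stats::rnorm(1, mean_, sqrt(1 / prec))

  # tau_alpha^2 (conjugate inverse gamma)
  current$tau_alpha2 <- max(.rinvgamma(
    1, priors$tau_alpha2[["shape"]] + J / 2,
    priors$tau_alpha2[["scale"]] +
      sum((coefs$alpha1 - current$mu_alpha)^2) / 2), .VAR_FLOOR)

  is_e <- group == "entity"
  b1 <- coefs$beta1
  sp <- states$S == 1

  # mu_beta1 components (all individuals carry a pre-spiral slope)
  for (g in .group_levels) {
    in_g <- group == g
    n_g <- sum(in_g)
    key <- paste0("mu_b1_", g)
    if (n_g == 0) {
      current$mu_beta1[[g]] <- stats::rnorm(1, priors$mu_beta1[["center"]],
                                            priors$mu_beta1[["sd"]])
      next
    }
    bg <- b1[in_g]
    tau1 <- sqrt(current$tau_beta1_sq)
    lp <- function(mu) {
      stats::dnorm(mu, priors$mu_beta1[["center"]],
                   priors$mu_beta1[["sd"]], log = TRUE) +
        sum(stats::dnorm(bg, mu, tau1, log = TRUE)) -
        n_g * stats::pnorm(mu / tau1, log.p = TRUE)
    }
    step <- .mh_step(current$mu_beta1[[g]], lp, prop_sd[[key]])
    current$mu_beta1[[g]] <- step$value
    acc[[key]] <- step$accepted
  }

  # tau_beta1^2 (log-scale Metropolis, all individuals)
  mu_g <- ifelse(is_e, current$mu_beta1[["entity"]],
                 current$mu_beta1[["incremental"]])
  lp_t1 <- function(lt) {
    t2 <- exp(lt); tau <- sqrt(t2)
    .ldinvgamma(t2, priors$tau_beta1_sq[["shape"]],
                priors$tau_beta1_sq[["scale"]]) + lt +
      sum(stats::dnorm(b1, mu_g, tau, log = TRUE)) -
      sum(stats::pnorm(mu_g / tau, log.p = TRUE))
  }
  step <- .mh_step(log(current$tau_beta1_sq), lp_t1, prop_sd[["log_tau_b1"]])
  current$tau_beta1_sq <- max(exp(step$value), .VAR_FLOOR)
  acc[["log_tau_b1"]] <- step$accepted

  # mu_beta2 components (spirallers only)
  for (g in .group_levels) {
    in_g <- group == g & sp
    n_g <- sum(in_g)
    key <- paste0("mu_b2_", g)
    if (n_g == 0) {
      current$mu_beta2[[g]] <- stats::rnorm(1, priors$mu_beta2[["center"]],
                                            priors$mu_beta2[["sd"]])
      next
    }
    bg <- coefs$beta2[in_g]
    tau2 <- sqrt(current$tau_beta2_sq)
    lp <- function(mu) {
      stats::dnorm(mu, priors$mu_beta2[["center"]],
                   priors$mu_beta2[["sd"]], log = TRUE) +
        sum(stats::dnorm(bg, mu, tau2, log = TRUE)) -
        n_g * stats::pnorm(-mu / tau2, log.p = TRUE)
    }
    step <- .mh_step(current$mu_beta2[[g]], lp, prop_sd[[key]])
    current$mu_beta2[[g]] <- step$value
    acc[[key]] <- step$accepted
  }

  # tau_beta2^2 (log-scale Metropolis, spirallers only)
  if (any(sp)) {
    b2s <- coefs$beta2[sp]
    mu2_g <- ifelse(is_e[sp], current$mu_beta2[["entity"]],
                    current$mu_beta2[["incremental"]])
    lp_t2 <- function(lt) {
      t2 <- exp(lt); tau <- sqrt(t2)
      .ldinvgamma(t2, priors$tau_beta2_sq[["shape"]],
                  priors$tau_beta2_sq[["scale"]]) + lt +
        sum(stats::dnorm(b2s, mu2_g, tau, log = TRUE)) -
        sum(stats::pnorm(-mu2_g / tau, log.p = TRUE))
    }
    step <- .mh_step(log(current$tau_beta2_sq), lp_t2,
                     prop_sd[["log_tau_b2"]])
    current$tau_beta2_sq <- max(exp(step$value), .VAR_FLOOR)
    acc[["log_tau_b2"]] <- step$accepted
  } else {
    current$tau_beta2_sq <- max(.rinvgamma(1, priors$tau_beta2_sq[["shape"]],
                                           priors$tau_beta2_sq[["scale"]]),
                                .VAR_FLOOR)
  }
  list(current = current, accepted = acc)
}

# --- the full sampler ------------------------------------------------------

#' Fit the spiral changepoint-mixture model by MCMC
#'
#' Runs the data-augmentation Gibbs sampler for the hierarchical spiral
#' model: per-individual latent spiral indicators and cut-points (updated
#' from their exact coefficient-marginalized conditional, giving exact
#' per-individual model averaging over the no-spiral model and all
#' `T - 2` spiral onsets), sign-constrained piecewise-linear trajectory
#' coefficients, logistic group spiral propensities, and all group-level
#' hyperparameters. Bit-reproducible given `seed`.
#'
#' @param cohort A cohort tibble ([as_cohort()]).
#' @param priors A `spiral_priors` object ([empirical_bayes_priors()]).
#' @param n_iter Total iterations.
#' @param burn_in Burn-in iterations (discarded; proposal tuning happens
#'   here).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed (required).
#' @param c_delta Optional override of the `delta` prior variance in
#'   `priors`.
#' @param prior_only If `TRUE`, the likelihood is disabled and the sampler
#'   targets the joint prior (for prior-recovery checks).
#' @param error `"normal"` or `"t"`; with `"t"`, per-observation latent
#'   scale variables give Student-t errors with `nu` degrees of freedom.
#' @param nu Degrees of freedom for `error = "t"`.
#' @return A tibble of retained draws, class `spiral_draws`: one row per
#'   retained iteration; group-level columns (`mu_alpha`, `tau_alpha2`,
#'   `sigma2`, `mu_beta1_entity`, ..., `delta_entity`, `pi_entity`, ...)
#'   and per-individual columns `S_<id>`, `c_<id>`, `alpha1_<id>`,
#'   `beta1_<id>`, `beta2_<id>`. Chain metadata (seed, burn-in, thinning,
#'   Metropolis acceptance rates, group labels) is attached as attributes.
#' @export
run_spiral_mcmc <- function(cohort, priors, n_iter = 50000,
                            burn_in = 10000, thin = 5, seed,
                            c_delta = NULL, prior_only = FALSE,
                            error = c("normal", "t"), nu = 5) {
  error <- match.arg(error)
  stopifnot(inherits(priors, "spiral_priors"), n_iter > burn_in)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  if (is.null(c_delta)) c_delta <- priors$c_delta

  d <- cohort_dims(cohort)
  y <- cohort_matrix(cohort)
  J <- d$J; T <- d$T
  group <- unname(d$group)
  group_is_entity <- group == "entity"
  ds <- .design_stats(T)
  w <- matrix(1, J, T)
  cs <- .cross_stats(y, w, ds)
  tmat <- matrix(ds$t, J, T, byrow = TRUE)

  # initialization from per-individual OLS (prior draws for prior-only runs)
  ols <- per_individual_ols(cohort)
  ols <- ols[match(d$ids, ols$individual), ]
  current <- list(
    mu_alpha = priors$mu_alpha[["center"]],
    tau_alpha2 = max(priors$tau_alpha2[["scale"]], .VAR_FLOOR),
    sigma2 = max(mean(ols$resid_var), .VAR_FLOOR),
    mu_beta1 = c(entity = priors$mu_beta1[["center"]],
                 incremental = priors$mu_beta1[["center"]]),
    mu_beta2 = c(entity = priors$mu_beta2[["center"]],
                 incremental = priors$mu_beta2[["center"]]),
    tau_beta1_sq = max(priors$tau_beta1_sq[["scale"]], .VAR_FLOOR),
    tau_beta2_sq = max(priors$tau_beta2_sq[["scale"]], .VAR_FLOOR)
  )
  delta <- c(entity = 0, incremental = 0)
  coefs <- tibble::tibble(alpha1 = ols$intercept,
                          beta1 = pmax(ols$slope, 0.1),
                          beta2 = rep(0, J))
  states <- tibble::tibble(S = rep(0L, J), cut = rep(NA_integer_, J))

  prop_sd <- c(mu_b1_entity = 0.3, mu_b1_incremental = 0.3,
               mu_b2_entity = 0.3, mu_b2_incremental = 0.3,
               log_tau_b1 = 0.4, log_tau_b2 = 0.4,
               delta_entity = 0.8, delta_incremental = 0.8)
  acc_count <- acc_total <- prop_sd * 0
  tune_count <- tune_total <- prop_sd * 0

  keep_iters <- seq(burn_in + thin, n_iter, by = thin)
  n_keep <- length(keep_iters)
  par_names <- c("mu_alpha", "tau_alpha2", "sigma2",
                 "mu_beta1_entity", "mu_beta1_incremental", "tau_beta1_sq",
                 "mu_beta2_entity", "mu_beta2_incremental", "tau_beta2_sq",
                 "delta_entity", "delta_incremental",
                 "pi_entity", "pi_incremental")
  ind_names <- c(paste0("S_", d$ids), paste0("c_", d$ids),
                 paste0("alpha1_", d$ids), paste0("beta1_", d$ids),
                 paste0("beta2_", d$ids))
  draws <- matrix(NA_real_, n_keep, length(par_names) + length(ind_names),
                  dimnames = list(NULL, c(par_names, ind_names)))
  row <- 0L

  for (iter in seq_len(n_iter)) {
    pi_j <- stats::plogis(ifelse(group_is_entity, delta[["entity"]],
                                 delta[["incremental"]]))

    hy <- list(mu_alpha = current$mu_alpha, tau_alpha2 = current$tau_alpha2,
               mu_beta1 = current$mu_beta1, tau_beta1_sq = current$tau_beta1_sq,
               mu_beta2 = current$mu_beta2, tau_beta2_sq = current$tau_beta2_sq)
    st <- .state_update(cs, ds, hy, group_is_entity, pi_j, current$sigma2,
                        prior_only = prior_only)
    states <- tibble::tibble(S = st$S, cut = st$cut)
    coefs <- .regen_coefficients(st)

    upd <- update_delta(delta, states$S, group, c_delta,
                        prop_sd[c("delta_entity", "delta_incremental")])
    delta <- upd$delta

    ceff <- ifelse(states$S == 1, states$cut, T + 1L)
    cmat <- matrix(ceff, J, T)
    M <- coefs$alpha1 + coefs$beta1 * pmin(tmat, cmat) +
      coefs$beta2 * pmax(tmat - cmat, 0)
    resid <- y - M
    if (error == "t" && !prior_only) {
      w <- matrix(stats::rgamma(J * T, (nu + 1) / 2,
                                rate = (nu + resid^2 / current$sigma2) / 2),
                  J, T)
      cs <- .cross_stats(y, w, ds)
    }
    resid_ss <- if (prior_only) 0 else sum(w * resid^2)
    n_obs <- if (prior_only) 0 else J * T

    uh <- update_hypers(coefs, states, group, priors, current,
                        resid_ss = resid_ss, n_obs = n_obs,
                        prop_sd = prop_sd[names(prop_sd) != "delta_entity" &
                                            names(prop_sd) != "delta_incremental"])
    current <- uh$current

    acc_now <- c(uh$accepted,
                 delta_entity = unname(upd$accepted[["entity"]]),
                 delta_incremental = unname(upd$accepted[["incremental"]]))
    live <- !is.na(acc_now[names(prop_sd)])
    if (iter <= burn_in) {
      tune_count[live] <- tune_count[live] + acc_now[names(prop_sd)][live]
      tune_total[live] <- tune_total[live] + 1
      if (iter %% 50 == 0) {
        rate <- ifelse(tune_total > 0, tune_count / tune_total, NA)
        adj <- !is.na(rate)
        prop_sd[adj] <- pmin(pmax(prop_sd[adj] * exp(1.5 * (rate[adj] - 0.3)),
                                  1e-3), 25)
        tune_count[] <- 0; tune_total[] <- 0
      }
    } else {
      acc_count[live] <- acc_count[live] + acc_now[names(prop_sd)][live]
      acc_total[live] <- acc_total[live] + 1
    }

    if (iter > burn_in && (iter - burn_in) %% thin == 0) {
      row <- row + 1L
      draws[row, ] <- c(
        current$mu_alpha, current$tau_alpha2, current$sigma2,
        current$mu_beta1[["entity"]], current$mu_beta1[["incremental"]],
        current$tau_beta1_sq,
        current$mu_beta2[["entity"]], current$mu_beta2[["incremental"]],
        current$tau_beta2_sq,
        delta[["entity"]], delta[["incremental"]],
        stats::plogis(delta[["entity"]]), stats::plogis(delta[["incremental"]]),
        states$S, ifelse(states$S == 1, states$cut, 0L),
        coefs$alpha1, coefs$beta1, coefs$beta2
      )
    }
  }

  out <- tibble::as_tibble(as.data.frame(draws))
  attr(out, "ids") <- d$ids
  attr(out, "labels") <- d$group
  attr(out, "T") <- T
  attr(out, "seed") <- seed
  attr(out, "n_iter") <- n_iter
  attr(out, "burn_in") <- burn_in
  attr(out, "thin") <- thin
  attr(out, "c_delta") <- c_delta
  attr(out, "prior_only") <- prior_only
  attr(out, "error") <- error
  attr(out, "acceptance") <-
    ifelse(acc_total > 0, acc_count / acc_total, NA)
  class(out) <- c("spiral_draws", class(out))
  out
}

#' Spiral model with Student-t errors
#'
#' Identical sampler with per-observation latent scale variables
#' (inverse-gamma mixing), giving `t_nu` observation errors; all
#' conditionals are adjusted by the latent precision weights.
#'
#' @inheritParams run_spiral_mcmc
#' @param nu Degrees of freedom (> 2).
#' @export
run_spiral_mcmc_t <- function(cohort, priors, n_iter = 50000,
                              burn_in = 10000, thin = 5, seed,
                              c_delta = NULL, nu = 5) {
  stopifnot(nu > 2)
  run_spiral_mcmc(cohort, priors, n_iter = n_iter, burn_in = burn_in,
                  thin = thin, seed = seed, c_delta = c_delta,
                  error = "t", nu = nu)
}
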