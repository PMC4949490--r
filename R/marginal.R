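# Exact coefficient-marginalized likelihood of the spiral states, and the
# per-individual 11-state full conditional built from it.
#
# Each individual has 1 + (T-2) candidate models: no spiral, or a spiral
# beginning at cut-point c in {1, ..., T-2}. Conditional on a state, the
# trajectory coefficients have (sign-constrained) normal priors, so the
# marginal likelihood is the unconstrained normal-normal marginal times the
# ratio of posterior to prior probability of the sign-constraint region.
# The posterior constraint term is a bivariate-normal quadrant probability
# over (beta1, beta2) after marginalizing the intercept; the prior term
# factorizes into univariate tails because the prior components are
# independent. This makes the (S, c) Gibbs update exact, which is what
# allows per-individual Bayesian model averaging over all 11 states.

#' Piecewise-linear design matrix for a spiral at cut-point `c`
#'
#' Row `t` is `(1, t, 0)` before the cut-point and `(1, c, t - c)` from it
#' on, i.e. columns `(1, min(t, c), max(t - c, 0))` for coefficients
#' `(alpha1, beta1, beta2)`. Both segment formulas agree at `t = c`, so the
#' implied mean is continuous there. `c = 1` is admissible: the second
#' column is then constant and the whole series is post-spiral.
#'
#' @param cut Cut-point in `1..(T-2)`.
#' @param T Number of trials.
#' @return A `T x 3` numeric matrix.
#' @export
piecewise_design <- function(cut, T) {
  if (length(cut) != 1 || cut < 1 || cut > T - 2 || cut != round(cut)) {
    stop("cut-point must be an integer in 1..(T-2)", call. = FALSE)
  }
  t <- seq_len(T)
  cbind(1, pmin(t, cut), pmax(t - cut, 0))
}

#' Per-individual hyperparameter set
#'
#' Bundles the group-resolved hyperparameters needed by the marginalized
#' state update for one individual: prior means and variances of
#' `(alpha1, beta1, beta2)`.
#'
#' @param mu_alpha,tau_alpha2 Intercept prior mean and variance.
#' @param mu_beta1,tau_beta1_sq Pre-spiral slope prior mean and variance
#'   (positive-truncated normal).
#' @param mu_beta2,tau_beta2_sq Post-spiral slope prior mean and variance
#'   (negative-truncated normal).
#' @return A named list.
#' @export
individual_hypers <- function(mu_alpha, tau_alpha2, mu_beta1, tau_beta1_sq,
                              mu_beta2, tau_beta2_sq) {
  stopifnot(tau_alpha2 > 0, tau_beta1_sq > 0, tau_beta2_sq > 0)
  list(mu_alpha = mu_alpha, tau_alpha2 = tau_alpha2,
       mu_beta1 = mu_beta1, tau_beta1_sq = tau_beta1_sq,
       mu_beta2 = mu_beta2, tau_beta2_sq = tau_beta2_sq)
}

#' Log marginal likelihood of one spiral state
#'
#' Integrates the trajectory coefficients out of the likelihood of one
#' individual's series under either the no-spiral model (`state = list(S =
#' 0)`; `beta2` is pinned at zero by its point-mass prior and only the
#' `beta1 > 0` constraint applies) or a spiral model (`state = list(S = 1,
#' cut = c)`; both sign constraints apply). Computed in log space; the
#' constraint-region probabilities are floored at `exp(-745)`.
#'
#' @param y Numeric vector, one score per trial.
#' @param state `list(S = 0)` or `list(S = 1, cut = c)`.
#' @param hypers An [individual_hypers()] list.
#' @param sigma2 Observation variance.
#' @param weights Optional per-trial precision weights (for the t-error
#'   scale mixture); default all 1.
#' @return Scalar log marginal likelihood.
#' @export
log_marginal <- function(y, state, hypers, sigma2, weights = NULL) {
  T <- length(y)
  stopifnot(sigma2 > 0, T >= 4)
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
  W <- weights
  XtWX <- crossprod(X * W, X)
  XtWy <- crossprod(X * W, y)
  A <- XtWX / sigma2 + diag(1 / v0, length(v0))
  Vn <- solve(A)
  mn <- drop(Vn %*% (XtWy / sigma2 + m0 / v0))
  r <- y - drop(X %*% m0)
  XtWr <- crossprod(X * W, r)
  quad <- sum(W * r^2) / sigma2 -
    drop(crossprod(XtWr, Vn %*% XtWr)) / sigma2^2
  logdet <- T * log(sigma2) - sum(log(W)) + sum(log(v0)) +
    determinant(A, logarithm = TRUE)$modulus
  log_unc <- -T / 2 * log(2 * pi) - logdet / 2 - quad / 2

  if (spiral) {
    s2 <- sqrt(Vn[2, 2]); s3 <- sqrt(Vn[3, 3])
    p_post <- pbvn_quadrant(mn[2], mn[3], s2, s3, Vn[2, 3] / (s2 * s3))
    p_prior <- stats::pnorm(hypers$mu_beta1 / sqrt(hypers$tau_beta1_sq)) *
      stats::pnorm(-hypers$mu_beta2 / sqrt(hypers$tau_beta2_sq))
  } else {
    p_post <- stats::pnorm(0, mn[2], sqrt(Vn[2, 2]), lower.tail = FALSE)
    p_prior <- stats::pnorm(hypers$mu_beta1 / sqrt(hypers$tau_beta1_sq))
  }
  as.numeric(log_unc + .log_floor(p_post) - .log_floor(p_prior))
}

#' Exact 11-state conditional distribution of the spiral state
#'
#' The full conditional of `(S_j, c_j)` given the hyperparameters, with the
#' trajectory coefficients integrated out: unnormalized masses are
#' `(1 - pi_j) * marginal(no spiral)` and `pi_j / (T - 2) * marginal(spiral
#' at c)` for each admissible `c`. Normalization is done with log-sum-exp.
#'
#' @inheritParams log_marginal
#' @param pi_j Spiral probability for this individual.
#' @return Tibble with columns `S`, `cut` (`NA` for the no-spiral state),
#'   `log_mass` (unnormalized) and `prob` (normalized; sums to 1).
#' @export
spiral_state_distribution <- function(y, hypers, sigma2, pi_j,
                                      weights = NULL) {
  stopifnot(pi_j >= 0, pi_j <= 1)
  T <- length(y)
  C <- T - 2
  lm0 <- log_marginal(y, list(S = 0), hypers, sigma2, weights)
  lmc <- vapply(seq_len(C), function(cc) {
    log_marginal(y, list(S = 1, cut = cc), hypers, sigma2, weights)
  }, numeric(1))
  log_mass <- c(.log_floor(1 - pi_j) + lm0,
                .log_floor(pi_j) - log(C) + lmc)
  if (all(!is.finite(log_mass))) {
    stop("all spiral-state masses are zero; model misconfigured",
         call. = FALSE)
  }
  m <- max(log_mass)
  prob <- exp(log_mass - m)
  prob <- prob / sum(prob)
  tibble::tibble(S = c(0L, rep(1L, C)),
                 cut = c(NA_integer_, seq_len(C)),
                 log_mass = log_mass,
                 prob = prob)
}

#' Draw spiral states from their exact full conditional
#'
#' @inheritParams spiral_state_distribution
#' @param n Number of independent draws.
#' @return Tibble with `n` rows and columns `S`, `cut`.
#' @export
sample_spiral_state <- function(y, hypers, sigma2, pi_j, n = 1,
                                weights = NULL) {
  dist <- spiral_state_distribution(y, hypers, sigma2, pi_j, weights)
  idx <- sample.int(nrow(dist), n, replace = TRUE, prob = dist$prob)
  tibble::tibble(S = dist$S[idx], cut = dist$cut[idx])
}
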