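# Independent quadrature oracle for the state marginal likelihood:
# alpha integrated analytically (y | b1,b2 ~ N(mu_a + b1 x2 + b2 x3,
# sigma2 I + tau_a2 J)), then Simpson integration over the truncated
# (b1, b2) grid. The Gaussian exponent is expanded as a quadratic form in
# (b1, b2) so the whole grid is vectorized.
quad_oracle <- function(y, state, hy, sigma2, n = 401) {
  T <- length(y)
  X <- if (state$S == 1) spiralmix::piecewise_design(state$cut, T) else cbind(1, seq_len(T), 0)
  x2 <- X[, 2]; x3 <- X[, 3]
  Sig <- diag(sigma2, T) + hy$tau_alpha2
  Si <- solve(Sig)
  r0 <- y - hy$mu_alpha
  ldet <- determinant(Sig, logarithm = TRUE)$modulus
  const <- -T / 2 * log(2 * pi) - ldet / 2
  A <- drop(r0 %*% Si %*% r0); B <- drop(r0 %*% Si %*% x2); C <- drop(r0 %*% Si %*% x3)
  D <- drop(x2 %*% Si %*% x2); E <- drop(x2 %*% Si %*% x3); F <- drop(x3 %*% Si %*% x3)
  t1 <- sqrt(hy$tau_beta1_sq); t2 <- sqrt(hy$tau_beta2_sq)
  logf <- function(b1, b2) {  # b1, b2 equal-length vectors (grid columns)
    q <- A - 2 * b1 * B - 2 * b2 * C + b1^2 * D + 2 * b1 * b2 * E + b2^2 * F
    const - q / 2 +
      stats::dnorm(b1, hy$mu_beta1, t1, log = TRUE) -
      stats::pnorm(hy$mu_beta1 / t1, log.p = TRUE) +
      (if (state$S == 1) {
        stats::dnorm(b2, hy$mu_beta2, t2, log = TRUE) -
          stats::pnorm(-hy$mu_beta2 / t2, log.p = TRUE)
      } else 0)
  }
  grid_eval <- function(g1, g2) {  # matrix length(g1) x length(g2)
    outer(seq_along(g1), seq_along(g2),
          function(i, j) logf(g1[i], g2[j]))
  }
  b1r <- seq(1e-8, hy$mu_beta1 + 10 * t1 + 10, length.out = 160)
  b2r <- if (state$S == 1) seq(hy$mu_beta2 - 10 * t2 - 10, -1e-8, length.out = 160) else 0
  L <- grid_eval(b1r, b2r)
  mx <- max(L)
  keep1 <- range(b1r[apply(L, 1, max) > mx - 35])
  simp <- function(n) { w <- rep(2, n); w[seq(2, n - 1, by = 2)] <- 4; w[1] <- w[n] <- 1; w }
  g1 <- seq(max(1e-10, keep1[1] - 0.5), keep1[2] + 0.5, length.out = n)
  if (state$S == 1) {
    keep2 <- range(b2r[apply(L, 2, max) > mx - 35])
    g2 <- seq(keep2[1] - 0.5, min(-1e-10, keep2[2] + 0.5), length.out = n)
    L2 <- grid_eval(g1, g2)
    m2 <- max(L2)
    w <- simp(n)
    log(sum(exp(L2 - m2) * outer(w, w))) + m2 +
      log(diff(g1[1:2]) / 3) + log(diff(g2[1:2]) / 3)
  } else {
    L2 <- logf(g1, rep(0, n))
    m2 <- max(L2)
    log(sum(exp(L2 - m2) * simp(n))) + m2 + log(diff(g1[1:2]) / 3)
  }
}
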