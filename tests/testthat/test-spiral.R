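test_that("coefficient draws satisfy the sign constraints surely", {
  set.seed(3)
  T <- 12
  hy <- individual_hypers(100, 5, 1.5, 0.8, -2, 0.8)
  y <- 100 + cumsum(c(rnorm(5, 2, 2), rnorm(7, -3, 2)))
  dr <- sample_coefficients(y, list(S = 1, cut = 5), hy, sigma2 = 9,
                            n = 10000)
  expect_true(all(dr$beta1 > 0))
  expect_true(all(dr$beta2 < 0))
  dr0 <- sample_coefficients(y, list(S = 0), hy, sigma2 = 9, n = 2000)
  expect_true(all(dr0$beta1 > 0))
  expect_true(all(dr0$beta2 == 0))
})

test_that("coefficient draws match a rejection-sampling oracle", {
  set.seed(11)
  T <- 8
  cc <- 4
  hy <- individual_hypers(100, 4, 1, 1.2, -1, 1.2)
  y <- 100 + cumsum(c(rnorm(cc, 1.5, 1.5), rnorm(T - cc, -2, 1.5)))
  sigma2 <- 4
  n <- 30000
  dr <- sample_coefficients(y, list(S = 1, cut = cc), hy, sigma2, n = n)

  # oracle: draw the unconstrained trivariate posterior with mvtnorm and
  # keep draws obeying the constraints
  X <- piecewise_design(cc, T)
  v0 <- c(hy$tau_alpha2, hy$tau_beta1_sq, hy$tau_beta2_sq)
  m0 <- c(hy$mu_alpha, hy$mu_beta1, hy$mu_beta2)
  A <- crossprod(X) / sigma2 + diag(1 / v0)
  Vn <- solve(A)
  mn <- drop(Vn %*% (crossprod(X, y) / sigma2 + m0 / v0))
  raw <- mvtnorm::rmvnorm(8 * n, mn, Vn)
  keep <- raw[raw[, 2] > 0 & raw[, 3] < 0, , drop = FALSE]
  expect_gt(nrow(keep), 1000)
  for (k in 1:3) {
    se <- sd(keep[, k]) * sqrt(1 / nrow(keep) + 1 / n)
    expect_lt(abs(mean(dr[[k]]) - mean(keep[, k])), 4 * se)
  }
})

test_that("delta update: no-data components come from the prior", {
  set.seed(2)
  delta <- c(entity = 0.3, incremental = -0.1)
  # all individuals incremental: the entity component has no data
  draws <- replicate(4000, {
    delta <<- update_delta(delta, S = c(1L, 0L, 0L),
                           group = rep("incremental", 3),
                           c_delta = 4)$delta
    delta[["entity"]]
  })
  expect_lt(abs(mean(draws)), 3 * sd(draws) / sqrt(4000))
  expect_lt(abs(sd(draws) - 2), 0.1)
})

test_that("delta update matches a grid-integration oracle", {
  set.seed(6)
  # 3 spirallers of 14 with a nearly flat prior
  S <- c(rep(1L, 3), rep(0L, 11))
  group <- rep("entity", 14)
  c_delta <- 100
  delta <- c(entity = 0, incremental = 0)
  n <- 20000
  out <- numeric(n)
  for (i in seq_len(n)) {
    delta <- update_delta(delta, S, group, c_delta, prop_sd = 1.2)$delta
    out[i] <- delta[["entity"]]
  }
  out <- out[-(1:2000)]
  dg <- seq(-15, 15, length.out = 20001)
  lp <- 3 * dg - 14 * log1p(exp(dg)) + dnorm(dg, 0, sqrt(c_delta), log = TRUE)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  expect_lt(abs(mean(plogis(out)) - sum(plogis(dg) * w)), 0.01)
  expect_lt(abs(mean(out) - sum(dg * w)), 0.05)
  expect_lt(abs(sd(out) - sqrt(sum(dg^2 * w) - sum(dg * w)^2)), 0.05)
})

test_that("delta components are exchangeable under symmetric data", {
  set.seed(8)
  S <- rep(c(1L, 0L), 7)                       # same counts in both groups
  group <- rep(c("entity", "incremental"), each = 7)
  S <- c(S[1:7], S[1:7])                       # identical patterns
  delta <- c(entity = 0, incremental = 0)
  diffs <- replicate(6000, {
    delta <<- update_delta(delta, S, group, 4, prop_sd = 1)$delta
    delta[["entity"]] - delta[["incremental"]]
  })
  expect_lt(abs(mean(diffs)), 4 * sd(diffs) / sqrt(2000))
})

test_that("sigma2 conditional reduces to IG(a + n/2, b) at zero residuals", {
  g <- study_like_fixture(seed = 41)
  pr <- empirical_bayes_priors(g$cohort)
  a <- pr$sigma2[["shape"]]; b <- pr$sigma2[["scale"]]
  coefs <- tibble::tibble(alpha1 = rep(100, 4), beta1 = rep(1, 4),
                          beta2 = rep(0, 4))
  states <- tibble::tibble(S = rep(0L, 4), cut = rep(NA_integer_, 4))
  grp <- rep(c("entity", "incremental"), 2)
  cur <- list(mu_alpha = 100, tau_alpha2 = 1, sigma2 = 1,
              mu_beta1 = c(entity = 1, incremental = 1),
              mu_beta2 = c(entity = -1, incremental = -1),
              tau_beta1_sq = 1, tau_beta2_sq = 1)
  set.seed(12)
  n_obs <- 24
  s2 <- replicate(6000, {
    update_hypers(coefs, states, grp, pr, cur,
                  resid_ss = 0, n_obs = n_obs)$current$sigma2
  })
  # precision is Gamma(a + n/2, b): compare first two moments
  sh <- a + n_obs / 2
  expect_lt(abs(mean(1 / s2) - sh / b), 4 * (sqrt(sh) / b) / sqrt(2000))
  expect_lt(abs(sd(1 / s2) - sqrt(sh) / b), 0.2 * sqrt(sh) / b)
})

test_that("slope-mean update agrees with conjugacy when truncation is slack", {
  # mu/tau > 6 so the truncated-normal normalizer is ~1; pin tau via a
  # near-degenerate IG prior and compare with the conjugate posterior
  g <- study_like_fixture(seed = 43)
  pr <- empirical_bayes_priors(g$cohort)
  tau2 <- 0.09
  pr$mu_beta1 <- c(center = 3, sd = 1)
  pr$tau_beta1_sq <- c(shape = 1e6, scale = (1e6 + 1) * tau2)
  pr$tau_beta2_sq <- c(shape = 1e6, scale = (1e6 + 1) * tau2)
  b1 <- c(2.8, 3.1, 3.3, 2.9, 3.0, 3.2)
  coefs <- tibble::tibble(alpha1 = rep(100, 6), beta1 = b1,
                          beta2 = rep(0, 6))
  states <- tibble::tibble(S = rep(0L, 6), cut = rep(NA_integer_, 6))
  grp <- rep("entity", 6)
  cur <- list(mu_alpha = 100, tau_alpha2 = 1, sigma2 = 25,
              mu_beta1 = c(entity = 3, incremental = 3),
              mu_beta2 = c(entity = -3, incremental = -3),
              tau_beta1_sq = tau2, tau_beta2_sq = tau2)
  set.seed(14)
  out <- numeric(8000)
  for (i in seq_along(out)) {
    cur <- update_hypers(coefs, states, grp, pr, cur,
                         resid_ss = 100, n_obs = 72)$current
    out[i] <- cur$mu_beta1[["entity"]]
  }
  out <- out[-(1:1000)]
  prec <- 1 / 1^2 + 6 / tau2
  post_mean <- (3 / 1^2 + sum(b1) / tau2) / prec
  post_sd <- sqrt(1 / prec)
  expect_lt(abs(mean(out) - post_mean), 4 * mcse_mean(out))
  expect_lt(abs(sd(out) - post_sd), 0.15 * post_sd)
})

test_that("the sampler is reproducible and keeps every draw consistent", {
  g <- generate_cohort(strong_signal_config(), seed = 7)
  pr <- empirical_bayes_priors(g$cohort)
  d1 <- run_spiral_mcmc(g$cohort, pr, n_iter = 300, burn_in = 100,
                        thin = 2, seed = 99)
  d2 <- run_spiral_mcmc(g$cohort, pr, n_iter = 300, burn_in = 100,
                        thin = 2, seed = 99)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_equal(nrow(d1), 100)

  ids <- attr(d1, "ids")
  for (id in ids) {
    S <- d1[[paste0("S_", id)]]
    cc <- d1[[paste0("c_", id)]]
    expect_true(all(d1[[paste0("beta1_", id)]] > 0))
    b2 <- d1[[paste0("beta2_", id)]]
    expect_true(all(b2[S == 1] < 0))
    expect_true(all(b2[S == 0] == 0))
    expect_true(all(cc[S == 1] %in% 1:10))
    expect_true(all(cc[S == 0] == 0))
  }
  # logistic transform is recorded consistently
  expect_equal(d1$pi_entity, plogis(d1$delta_entity))
})

test_that("swapping group labels swaps the propensity posteriors", {
  g <- generate_cohort(strong_signal_config(
    pi = c(entity = 0.7, incremental = 0.1)), seed = 15)
  pr <- empirical_bayes_priors(g$cohort)
  swapped <- g$cohort
  swapped$group <- ifelse(swapped$group == "entity", "incremental", "entity")
  swapped <- as_cohort(swapped)
  d1 <- run_spiral_mcmc(g$cohort, pr, n_iter = 1200, burn_in = 400,
                        thin = 1, seed = 5)
  d2 <- run_spiral_mcmc(swapped, empirical_bayes_priors(swapped),
                        n_iter = 1200, burn_in = 400, thin = 1, seed = 6)
  expect_lt(abs(mean(d1$pi_entity) - mean(d2$pi_incremental)), 0.1)
  expect_lt(abs(mean(d1$pi_incremental) - mean(d2$pi_entity)), 0.1)
  # slope means mix by Metropolis, so compare at Monte-Carlo resolution
  se <- sqrt(mcse_mean(d1$mu_beta1_entity)^2 +
               mcse_mean(d2$mu_beta1_incremental)^2)
  expect_lt(abs(mean(d1$mu_beta1_entity) - mean(d2$mu_beta1_incremental)),
            max(4 * se, 0.3))
})

test_that("t-error sampler approaches the normal sampler for large nu", {
  g <- generate_cohort(strong_signal_config(), seed = 33)
  pr <- empirical_bayes_priors(g$cohort)
  dn <- run_spiral_mcmc(g$cohort, pr, n_iter = 1500, burn_in = 500,
                        thin = 1, seed = 4)
  dt <- run_spiral_mcmc_t(g$cohort, pr, n_iter = 1500, burn_in = 500,
                          thin = 1, seed = 4, nu = 1e6)
  pn <- spiral_table(dn)$individuals$pr_spiral
  pt <- spiral_table(dt)$individuals$pr_spiral
  expect_lt(max(abs(pn - pt)), 0.12)
  expect_lt(abs(mean(dn$sigma2) - mean(dt$sigma2)), 1.5)
})
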