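test_that("baseline Gibbs recovers its priors when the likelihood is off", {
  g <- study_like_fixture(seed = 51)
  pr <- empirical_bayes_priors(g$cohort)
  dr <- gibbs_lcm(g$cohort, pr, n_iter = 6000, burn_in = 500, seed = 2,
                  prior_only = TRUE)
  expect_lt(abs(mean(dr$mu_alpha) - pr$mu_alpha[["center"]]),
            3 * mcse_mean(dr$mu_alpha))
  expect_lt(abs(sd(dr$mu_alpha) - pr$mu_alpha[["sd"]]),
            0.1 * pr$mu_alpha[["sd"]])
  expect_lt(abs(mean(dr$mu_E) - pr$mu_beta[["center"]]),
            3 * mcse_mean(dr$mu_E))
  # precision of the observation noise is Gamma(shape, rate = scale)
  a <- pr$sigma2[["shape"]]; b <- pr$sigma2[["scale"]]
  expect_lt(abs(mean(1 / dr$sigma2) - a / b), 4 * (sqrt(a) / b) / sqrt(2000))
})

test_that("individual coefficients match the conjugate closed form", {
  # hyperparameters pinned by near-degenerate priors, so the (alpha, beta)
  # conditional is a plain normal-normal posterior we can write down
  co <- toy_cohort(J = 2, T = 12, slopes = c(1.2, 0.4),
                   intercepts = c(101, 99), noise = 3)
  pr <- empirical_bayes_priors(co)
  s2 <- 4; ta2 <- 9; tb2 <- 1
  pr$mu_alpha <- c(center = 100, sd = 1e-6)
  pr$mu_beta <- c(center = 1, sd = 1e-6)
  pr$sigma2 <- c(shape = 1e6, scale = (1e6 + 1) * s2)
  pr$tau_alpha2 <- c(shape = 1e6, scale = (1e6 + 1) * ta2)
  pr$tau_beta2_lcm <- c(shape = 1e6, scale = (1e6 + 1) * tb2)
  dr <- gibbs_lcm(co, pr, n_iter = 12000, burn_in = 2000, seed = 9)
  y <- co$score[co$individual == "01"]
  X <- cbind(1, 1:12)
  A <- crossprod(X) / s2 + diag(1 / c(ta2, tb2))
  Vn <- solve(A)
  mn <- drop(Vn %*% (crossprod(X, y) / s2 + c(100 / ta2, 1 / tb2)))
  expect_lt(abs(mean(dr$alpha_01) - mn[1]), 4 * mcse_mean(dr$alpha_01))
  expect_lt(abs(mean(dr$beta_01) - mn[2]), 4 * mcse_mean(dr$beta_01))
  expect_lt(abs(sd(dr$alpha_01) - sqrt(Vn[1, 1])), 0.1 * sqrt(Vn[1, 1]))
  expect_lt(abs(sd(dr$beta_01) - sqrt(Vn[2, 2])), 0.1 * sqrt(Vn[2, 2]))
})

test_that("REML collapses to the common OLS line on degenerate data", {
  co <- as_cohort(tibble::tibble(
    individual = rep(sprintf("%02d", 1:6), each = 12),
    group = rep(c("entity", "incremental"), each = 36),
    trial = rep(1:12, 6),
    score = rep(100 + 1.5 * (1:12), 6)))
  fit <- suppressWarnings(fit_lcm_ml(co))
  est <- fit$estimates
  expect_equal(est$estimate[est$term == "mu_alpha"], 100, tolerance = 1e-6)
  expect_equal(est$estimate[est$term == "mu_E"], 1.5, tolerance = 1e-6)
  expect_equal(est$estimate[est$term == "mu_I"], 1.5, tolerance = 1e-6)
  expect_true(all(fit$varcomp$variance < 1e-6))
})

test_that("REML recovers generator truth across replicates", {
  # the realized slope-mean truth is the mean of the positive-truncated
  # normal the generator draws from (tight tau, so truncation is mild)
  tn_mean <- function(mu, s) mu + s * dnorm(-mu / s) / (1 - pnorm(-mu / s))
  cfg <- generator_config(pi = c(entity = 0, incremental = 0),
                          mu_beta1 = c(entity = 0.3, incremental = 1.7),
                          tau_beta1 = 0.3, sigma = 5)
  true_E <- tn_mean(0.3, 0.3)
  true_I <- tn_mean(1.7, 0.3)
  hits <- vapply(1:40, function(s) {
    g <- generate_cohort(cfg, seed = 300 + s)
    fit <- suppressWarnings(fit_lcm_ml(g$cohort))
    est <- fit$estimates
    eE <- est[est$term == "mu_E", ]
    eI <- est[est$term == "mu_I", ]
    c(abs(eE$estimate - true_E) < 2 * eE$se,
      abs(eI$estimate - true_I) < 2 * eI$se)
  }, logical(2))
  expect_gte(mean(hits), 0.9)
})

test_that("per-group intercept flag yields separate intercept estimates", {
  g <- study_like_fixture(seed = 53)
  fit <- fit_lcm_ml(g$cohort, per_group_intercept = TRUE)
  expect_setequal(
    fit$estimates$term,
    c("mu_alpha_entity", "mu_alpha_incremental", "mu_E", "mu_I"))
})

test_that("slope contrast summarizes draw-wise differences", {
  draws <- tibble::tibble(mu_E = c(-1, -2, -0.5), mu_I = c(0, 0, 0))
  class(draws) <- c("lcm_draws", class(draws))
  sc <- slope_contrast(draws)
  expect_equal(sc$frac_below_zero, 1)
  expect_equal(sum(sc$hist$count), 3)
  # antisymmetry: exchanging the groups negates the contrast exactly
  swapped <- tibble::tibble(mu_E = draws$mu_I, mu_I = draws$mu_E)
  class(swapped) <- c("lcm_draws", class(swapped))
  expect_equal(slope_contrast(swapped)$diffs, -sc$diffs)
})

test_that("a strong learning-rate gap is detected by the contrast", {
  # group slope means ~1.4 apart (the tight tau keeps truncation mild)
  cfg <- generator_config(pi = c(entity = 0, incremental = 0),
                          mu_beta1 = c(entity = 0.3, incremental = 1.7),
                          tau_beta1 = 0.3, sigma = 5)
  g <- generate_cohort(cfg, seed = 61)
  pr <- empirical_bayes_priors(g$cohort)
  dr <- gibbs_lcm(g$cohort, pr, n_iter = 4000, burn_in = 1000, seed = 3)
  expect_gte(slope_contrast(dr)$frac_below_zero, 0.9)
})
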