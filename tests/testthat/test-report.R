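test_that("spiral table summary arithmetic is exact on the worked example", {
  tab <- example_spiral_table()
  expect_equal(nrow(tab), 28)
  smry <- summarize_spiral_table(tab)
  ent <- smry[smry$group == "entity", ]
  inc <- smry[smry$group == "incremental", ]
  expect_equal(round(ent$avg_pr_spiral, 2), 0.62)
  expect_equal(round(inc$avg_pr_spiral, 2), 0.18)
  expect_equal(inc$n_spirallers, 1)
  # group averages equal recomputed means of the individual column
  expect_equal(ent$avg_pr_spiral,
               mean(tab$pr_spiral[tab$group == "entity"]))
  expect_equal(ent$n_spirallers + ent$n_non_spirallers, 14L)
})

test_that("spiral_table computes probabilities and the 0-convention", {
  ids <- c("01", "02", "03")
  labels <- c("entity", "entity", "incremental")
  # 01 spirals in 3/4 draws at cut 4; 02 never; 03 spirals 1/4 at cut 2
  dr <- fake_spiral_draws(
    n = 4, ids, labels,
    S = list(c(1, 1, 1, 0), 0, c(1, 0, 0, 0)),
    cuts = list(c(4, 4, 5, 0), 0, c(2, 0, 0, 0)),
    alpha1 = list(100, 100, 100), beta1 = list(2, 2, 2),
    beta2 = list(c(-3, -3, -3, 0), 0, c(-1, 0, 0, 0)))
  rep <- spiral_table(dr)
  expect_equal(rep$individuals$pr_spiral, c(0.75, 0, 0.25))
  expect_equal(rep$individuals$c_hat, c(4, 0, 0))
  expect_equal(rep$groups$avg_pr_spiral[rep$groups$group == "entity"], 0.375)
  # degenerate all-no-spiral chain
  dr0 <- fake_spiral_draws(n = 5, ids, labels,
                           S = list(0, 0, 0), cuts = list(0, 0, 0),
                           alpha1 = list(100, 100, 100),
                           beta1 = list(2, 2, 2), beta2 = list(0, 0, 0))
  rep0 <- spiral_table(dr0)
  expect_true(all(rep0$individuals$pr_spiral == 0))
  expect_true(all(rep0$individuals$c_hat == 0))
})

test_that("pi contrast transforms delta draws and is antisymmetric", {
  dr <- fake_spiral_draws(
    n = 6, ids = "01", labels = "entity", S = list(0), cuts = list(0),
    alpha1 = list(100), beta1 = list(2), beta2 = list(0),
    extras = list(delta_entity = c(1, 2, 0.5, 1, 3, 0.2),
                  delta_incremental = c(0, 1, 0, 0.5, 2, 0)))
  pc <- pi_contrast(dr)
  expect_equal(pc$frac_entity_above, 1)           # pairwise dominance
  expect_equal(pc$diffs,
               plogis(dr$delta_entity) - plogis(dr$delta_incremental))
  # identical components give identically zero differences
  dr2 <- fake_spiral_draws(
    n = 4, ids = "01", labels = "entity", S = list(0), cuts = list(0),
    alpha1 = list(100), beta1 = list(2), beta2 = list(0),
    extras = list(delta_entity = c(-1, 0, 1, 2),
                  delta_incremental = c(-1, 0, 1, 2)))
  pc2 <- pi_contrast(dr2)
  expect_true(all(pc2$diffs == 0))
  # the three fractions partition all draws
  expect_equal(pc$frac_entity_above + pc$frac_incremental_above +
                 pc$frac_tied, 1)
  expect_equal(pc2$frac_tied, 1)
})

test_that("model-averaged trajectories mix the per-state lines exactly", {
  # all draws no-spiral: the fitted curve is exactly linear
  dr0 <- fake_spiral_draws(n = 10, ids = "01", labels = "entity",
                           S = list(0), cuts = list(0),
                           alpha1 = list(100), beta1 = list(1.5),
                           beta2 = list(0))
  ft <- fitted_trajectory(dr0, "01")
  expect_equal(ft$trajectory$mean, 100 + 1.5 * (1:12))
  expect_equal(ft$cut_pmf$prob[ft$cut_pmf$cut == 0], 1)

  # all draws one spiral state: exactly the kinked line
  dr1 <- fake_spiral_draws(n = 10, ids = "01", labels = "entity",
                           S = list(1), cuts = list(4),
                           alpha1 = list(100), beta1 = list(2),
                           beta2 = list(-3))
  ft1 <- fitted_trajectory(dr1, "01")
  expect_equal(ft1$trajectory$mean,
               trajectory_mean(1:12, 100, 2, -3, S = 1, cut = 4))
  expect_equal(ft1$pr_spiral, 1)

  # mixed three-state chain: equals the enumeration-weighted average
  S <- c(0, 1, 1, 1, 0, 1)
  cuts <- c(0, 3, 3, 6, 0, 6)
  dr2 <- fake_spiral_draws(n = 6, ids = "01", labels = "entity",
                           S = list(S), cuts = list(cuts),
                           alpha1 = list(100), beta1 = list(2),
                           beta2 = list(c(0, -3, -3, -1, 0, -1)))
  ft2 <- fitted_trajectory(dr2, "01")
  states <- list(list(S = 0, c = 0, b2 = 0, w = 2 / 6),
                 list(S = 1, c = 3, b2 = -3, w = 2 / 6),
                 list(S = 1, c = 6, b2 = -1, w = 2 / 6))
  manual <- Reduce(`+`, lapply(states, function(st) {
    st$w * trajectory_mean(1:12, 100, 2, st$b2, st$S,
                           if (st$c == 0) 1 else st$c)
  }))
  expect_equal(ft2$trajectory$mean, manual)
  # convexity: between the per-state extremes at every trial
  per_state <- sapply(states, function(st) {
    trajectory_mean(1:12, 100, 2, st$b2, st$S, if (st$c == 0) 1 else st$c)
  })
  expect_true(all(ft2$trajectory$mean >= apply(per_state, 1, min) - 1e-12))
  expect_true(all(ft2$trajectory$mean <= apply(per_state, 1, max) + 1e-12))
  expect_equal(sum(ft2$cut_pmf$prob), 1)
})

test_that("the induced prior on the spiral propensity is analytic", {
  # strongly equalizing prior: ~95% mass on [0.45, 0.55]
  expect_equal(prior_induced_pi(0.01, c(0.45, 0.55)), 0.9552, tolerance = 1e-3)
  # symmetry of the zero-mean prior around 1/2
  for (cd in c(0.01, 1, 4, 25)) {
    expect_equal(prior_induced_pi(cd, c(1e-15, 0.5)), 0.5, tolerance = 1e-9)
    expect_equal(prior_induced_pi(cd, c(0.3, 0.45)),
                 prior_induced_pi(cd, c(0.55, 0.7)), tolerance = 1e-12)
  }
  # c_delta = 4 is approximately uniform: max CDF deviation ~0.04
  p <- seq(0.001, 0.999, by = 0.0005)
  dev <- max(abs(pnorm(qlogis(p) / 2) - p))
  expect_lt(abs(dev - 0.044), 0.01)
  expect_error(prior_induced_pi(4, c(0.7, 0.3)), "interval")
  expect_error(prior_induced_pi(-1, c(0.3, 0.7)))
})

test_that("a one-point sensitivity grid reproduces a plain fit", {
  g <- generate_cohort(strong_signal_config(), seed = 71)
  pr <- empirical_bayes_priors(g$cohort)
  sw <- sensitivity_sweep(g$cohort, pr, c_delta_grid = 2,
                          n_iter = 400, burn_in = 100, seed = 13)
  direct <- run_spiral_mcmc(g$cohort, pr, n_iter = 400, burn_in = 100,
                            thin = 1, seed = 13, c_delta = 2)
  expect_equal(sw$pr_entity_above, pi_contrast(direct)$frac_entity_above)
  expect_true(sw$ok)
})

test_that("tidiers and plots return the expected shapes", {
  g <- generate_cohort(strong_signal_config(), seed = 73)
  pr <- empirical_bayes_priors(g$cohort)
  dr <- run_spiral_mcmc(g$cohort, pr, n_iter = 300, burn_in = 100,
                        thin = 1, seed = 1)
  td <- tidy(dr)
  expect_true(all(c("term", "estimate", "std.error", "conf.low",
                    "conf.high") %in% names(td)))
  expect_true("pi_entity" %in% td$term)
  gl <- glance(dr)
  expect_equal(gl$n_draws, nrow(dr))
  expect_s3_class(autoplot(g$cohort), "ggplot")
  expect_s3_class(autoplot(spiral_table(dr)), "ggplot")
  expect_s3_class(plot_trajectory(dr, "01", g$cohort), "ggplot")
  expect_s3_class(autoplot(pi_contrast(dr)), "ggplot")
  ml <- fit_lcm_ml(g$cohort)
  expect_true(all(c("term", "estimate", "std.error") %in% names(tidy(ml))))
  expect_true("sigma2" %in% names(glance(ml)))
})
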