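# Shared fixtures, built in code at test time.

# a small, fully deterministic cohort: straight lines plus fixed jitter
toy_cohort <- function(J = 4, T = 6, slopes = NULL, intercepts = NULL,
                       noise = 0) {
  if (is.null(slopes)) slopes <- seq(0.5, 2, length.out = J)
  if (is.null(intercepts)) intercepts <- seq(98, 104, length.out = J)
  ids <- sprintf("%02d", seq_len(J))
  grp <- rep(c("entity", "incremental"), length.out = J)
  rows <- lapply(seq_len(J), function(j) {
    tibble::tibble(individual = ids[j], group = grp[j], trial = 1:T,
                   score = intercepts[j] + slopes[j] * (1:T) +
                     noise * sin(seq_len(T) + j))
  })
  as_cohort(dplyr::bind_rows(rows))
}

# strong-signal generator settings used by the recovery checks:
# steep post-spiral decline, low noise
strong_signal_config <- function(pi = c(entity = 0.6, incremental = 0.15)) {
  generator_config(mu_beta2 = c(entity = -4, incremental = -4),
                   tau_beta2 = 0.5, sigma = 3, pi = pi)
}

# minimal spiral_draws object with specified per-individual draw columns,
# for exercising report summaries without running the sampler
fake_spiral_draws <- function(n, ids, labels, S, cuts, alpha1, beta1, beta2,
                              extras = list()) {
  cols <- list()
  base <- list(mu_alpha = 100, tau_alpha2 = 1, sigma2 = 1,
               mu_beta1_entity = 1, mu_beta1_incremental = 1,
               tau_beta1_sq = 1, mu_beta2_entity = -1,
               mu_beta2_incremental = -1, tau_beta2_sq = 1,
               delta_entity = 0, delta_incremental = 0,
               pi_entity = 0.5, pi_incremental = 0.5)
  base[names(extras)] <- extras
  for (nm in names(base)) cols[[nm]] <- rep_len(base[[nm]], n)
  for (k in seq_along(ids)) {
    id <- ids[k]
    cols[[paste0("S_", id)]] <- rep_len(S[[k]], n)
    cols[[paste0("c_", id)]] <- rep_len(cuts[[k]], n)
    cols[[paste0("alpha1_", id)]] <- rep_len(alpha1[[k]], n)
    cols[[paste0("beta1_", id)]] <- rep_len(beta1[[k]], n)
    cols[[paste0("beta2_", id)]] <- rep_len(beta2[[k]], n)
  }
  out <- tibble::as_tibble(cols)
  attr(out, "ids") <- ids
  attr(out, "labels") <- stats::setNames(labels, ids)
  attr(out, "T") <- 12
  attr(out, "seed") <- 0
  attr(out, "n_iter") <- n
  attr(out, "burn_in") <- 0
  attr(out, "thin") <- 1
  class(out) <- c("spiral_draws", class(out))
  out
}

# random per-individual hyperparameter sets for property loops
random_hypers <- function() {
  individual_hypers(
    mu_alpha = stats::runif(1, 95, 105),
    tau_alpha2 = stats::runif(1, 2, 10),
    mu_beta1 = stats::runif(1, 0.5, 3),
    tau_beta1_sq = stats::runif(1, 0.3, 2),
    mu_beta2 = stats::runif(1, -4, -0.5),
    tau_beta2_sq = stats::runif(1, 0.3, 2)
  )
}

# evaluate each cohort row's noiseless mean from the recorded ground truth
trajectory_mean_rowwise <- function(truth, cohort) {
  idx <- match(cohort$individual, truth$individual)
  mapply(function(t, k) {
    trajectory_mean(t, truth$alpha1[k], truth$beta1[k], truth$beta2[k],
                    truth$S[k],
                    if (is.na(truth$cut[k])) 1L else truth$cut[k])
  }, cohort$trial, idx)
}
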