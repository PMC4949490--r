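# Posterior summaries: per-individual spiral reports, group contrasts,
# model-averaged trajectories, the prior-sensitivity sweep, and the
# analytic prior induced on the spiral probabilities.

#' Summarize a per-individual spiral table
#'
#' Computes the group-level summary arithmetic from a per-individual table
#' of spiral probabilities: group averages of `pr_spiral`, counts above and
#' not above the 0.5 threshold per group.
#'
#' @param tab Tibble with columns `individual`, `group`, `pr_spiral` and
#'   optionally `c_hat`.
#' @return Tibble with one row per group: `group`, `avg_pr_spiral`,
#'   `n_spirallers` (`pr_spiral > 0.5`), `n_non_spirallers`, `n`.
#' @export
summarize_spiral_table <- function(tab) {
  stopifnot(all(c("individual", "group", "pr_spiral") %in% names(tab)))
  stopifnot(all(tab$pr_spiral >= 0 & tab$pr_spiral <= 1))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(tab), .data$group),
    avg_pr_spiral = mean(.data$pr_spiral),
    n_spirallers = sum(.data$pr_spiral > 0.5),
    n_non_spirallers = sum(.data$pr_spiral <= 0.5),
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' Per-individual spiral report from posterior draws
#'
#' For each individual: the posterior spiral probability (retained-draw mean
#' of `S_j`), and the posterior median cut-point given `S_j = 1`, reported
#' as 0 when the spiral probability is not above 0.5. Group summaries and
#' the two headline contrasts (fraction of draws with the entity pre-spiral
#' slope mean below the incremental one, and with `pi_E > pi_I`) are
#' attached.
#'
#' @param draws A `spiral_draws` tibble.
#' @return List of class `spiral_report`: `individuals` (tibble
#'   `individual`, `group`, `pr_spiral`, `c_hat`), `groups`
#'   (see [summarize_spiral_table()]), `contrasts` (tibble).
#' @export
spiral_table <- function(draws) {
  stopifnot(inherits(draws, "spiral_draws"))
  ids <- attr(draws, "ids")
  labels <- attr(draws, "labels")
  per <- purrr::map_dfr(ids, function(id) {
    S <- draws[[paste0("S_", id)]]
    cc <- draws[[paste0("c_", id)]]
    pr <- mean(S)
    c_hat <- if (pr > 0.5) stats::median(cc[S == 1]) else 0
    tibble::tibble(individual = id, group = unname(labels[id]),
                   pr_spiral = pr, c_hat = c_hat)
  })
  contrasts <- tibble::tibble(
    frac_slope_entity_below = mean(draws$mu_beta1_entity <
                                     draws$mu_beta1_incremental),
    frac_pi_entity_above = mean(draws$pi_entity > draws$pi_incremental)
  )
  out <- list(individuals = per,
              groups = summarize_spiral_table(per),
              contrasts = contrasts)
  class(out) <- "spiral_report"
  out
}

#' @export
print.spiral_report <- function(x, ...) {
  cat("Spiral report\n")
  print(x$individuals, n = Inf)
  print(x$groups)
  print(x$contrasts)
  invisible(x)
}

#' Posterior contrast of the group spiral probabilities
#'
#' Transforms each retained `delta` draw through the logistic function and
#' summarizes `pi_E - pi_I`: the draw-wise differences, the fraction of
#' draws with `pi_E > pi_I`, and histogram bin counts.
#'
#' @param draws A `spiral_draws` tibble.
#' @param bins Number of histogram bins.
#' @return List of class `pi_contrast`: `diffs`, `frac_entity_above`,
#'   `frac_incremental_above`, `frac_tied`, `hist`.
#' @export
pi_contrast <- function(draws, bins = 40) {
  pi_e <- stats::plogis(draws$delta_entity)
  pi_i <- stats::plogis(draws$delta_incremental)
  diffs <- pi_e - pi_i
  h <- graphics::hist(diffs, breaks = bins, plot = FALSE)
  out <- list(diffs = diffs,
              frac_entity_above = mean(diffs > 0),
              frac_incremental_above = mean(diffs < 0),
              frac_tied = mean(diffs == 0),
              hist = tibble::tibble(mid = h$mids, count = h$counts))
  class(out) <- "pi_contrast"
  out
}

#' Model-averaged fitted trajectory for one individual
#'
#' The posterior mean trajectory `E(yhat_tj | Y)` is the draw-average of
#' the piecewise-linear mean at each trial — averaging over spiral states
#' and cut-points as well as coefficients, so the result is generally not
#' piecewise linear itself. Also returns the posterior probability mass
#' function of the cut-point.
#'
#' @param draws A `spiral_draws` tibble.
#' @param individual Individual id (as in the cohort).
#' @return List: `trajectory` (tibble `trial`, `mean`), `cut_pmf` (tibble
#'   `cut`, `prob`, including `cut = 0` for the no-spiral state),
#'   `pr_spiral`.
#' @export
fitted_trajectory <- function(draws, individual) {
  stopifnot(inherits(draws, "spiral_draws"))
  id <- as.character(individual)
  if (!paste0("S_", id) %in% names(draws)) {
    stop("unknown individual: ", id, call. = FALSE)
  }
  T <- attr(draws, "T")
  S <- draws[[paste0("S_", id)]]
  cc <- draws[[paste0("c_", id)]]
  a1 <- draws[[paste0("alpha1_", id)]]
  b1 <- draws[[paste0("beta1_", id)]]
  b2 <- draws[[paste0("beta2_", id)]]
  ceff <- ifelse(S == 1, cc, T + 1)
  mean_t <- vapply(seq_len(T), function(t) {
    mean(a1 + b1 * pmin(t, ceff) + b2 * pmax(t - ceff, 0))
  }, numeric(1))
  pmf <- table(factor(ifelse(S == 1, cc, 0), levels = 0:(T - 2)))
  list(
    trajectory = tibble::tibble(trial = seq_len(T), mean = mean_t),
    cut_pmf = tibble::tibble(cut = 0:(T - 2),
                             prob = as.numeric(pmf) / length(S)),
    pr_spiral = mean(S)
  )
}

#' Sensitivity of the propensity contrast to the delta prior variance
#'
#' Refits the spiral model at each value of `c_delta` on a grid (same data,
#' priors, chain settings and seed policy) and records the posterior
#' probability that the entity spiral propensity exceeds the incremental
#' one. As `c_delta -> 0` the prior forces the two propensities together
#' and the curve approaches 0.5.
#'
#' @param cohort A cohort tibble.
#' @param priors A `spiral_priors` object.
#' @param c_delta_grid Positive grid values.
#' @param n_iter,burn_in,thin,seed Chain control passed to
#'   [run_spiral_mcmc()].
#' @return Tibble of class `sensitivity_curve`: `c_delta`,
#'   `pr_entity_above`, `ok` (FALSE where a fit failed).
#' @export
sensitivity_sweep <- function(cohort, priors, c_delta_grid,
                              n_iter = 4000, burn_in = 1000, thin = 1,
                              seed = 1) {
  stopifnot(all(c_delta_grid > 0))
  rows <- purrr::map(c_delta_grid, function(cd) {
    res <- tryCatch({
      dr <- run_spiral_mcmc(cohort, priors, n_iter = n_iter,
                            burn_in = burn_in, thin = thin, seed = seed,
                            c_delta = cd)
      tibble::tibble(c_delta = cd,
                     pr_entity_above = pi_contrast(dr)$frac_entity_above,
                     ok = TRUE)
    }, error = function(e) {
      warning("fit failed at c_delta = ", cd, ": ", conditionMessage(e),
              call. = FALSE)
      tibble::tibble(c_delta = cd, pr_entity_above = NA_real_, ok = FALSE)
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sensitivity_curve", class(out))
  out
}

#' Prior probability that a spiral propensity lies in an interval
#'
#' Under the prior `delta ~ N(0, c_delta)`, the induced prior on
#' `pi = plogis(delta)` gives `P(a < pi < b) =
#' Phi(logit(b) / sqrt(c_delta)) - Phi(logit(a) / sqrt(c_delta))`.
#' With `c_delta = 0.01` the interval `[0.45, 0.55]` carries ~95% prior
#' mass (a strongly equalizing prior); `c_delta = 4` makes the induced
#' distribution approximately uniform on (0, 1).
#'
#' @param c_delta Prior variance (> 0).
#' @param interval Length-2 numeric, `0 < a < b < 1`.
#' @return Scalar probability.
#' @export
prior_induced_pi <- function(c_delta, interval) {
  stopifnot(c_delta > 0, length(interval) == 2)
  a <- interval[1]; b <- interval[2]
  if (!(a > 0 && b < 1 && a < b)) {
    stop("interval must satisfy 0 < a < b < 1", call. = FALSE)
  }
  s <- sqrt(c_delta)
  stats::pnorm(stats::qlogis(b) / s) - stats::pnorm(stats::qlogis(a) / s)
}
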