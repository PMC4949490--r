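# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

.summarize_cols <- function(draws, cols) {
  purrr::map_dfr(cols, function(cl) {
    x <- draws[[cl]]
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    tibble::tibble(term = cl, estimate = mean(x), std.error = stats::sd(x),
                   conf.low = q[1], conf.high = q[2])
  })
}

#' Tidy posterior summaries of a spiral-model fit
#'
#' One row per group-level parameter: posterior mean, SD and central 95%
#' credible interval over the retained draws.
#'
#' @param x A `spiral_draws` tibble.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy spiral_draws
#' @export
tidy.spiral_draws <- function(x, ...) {
  cols <- c("mu_alpha", "tau_alpha2", "sigma2",
            "mu_beta1_entity", "mu_beta1_incremental", "tau_beta1_sq",
            "mu_beta2_entity", "mu_beta2_incremental", "tau_beta2_sq",
            "delta_entity", "delta_incremental", "pi_entity",
            "pi_incremental")
  .summarize_cols(x, cols)
}

#' @rdname tidy.spiral_draws
#' @method tidy lcm_draws
#' @export
tidy.lcm_draws <- function(x, ...) {
  .summarize_cols(x, c("mu_alpha", "mu_E", "mu_I", "tau_alpha2",
                       "tau_beta2", "sigma2"))
}

#' Chain-level summary of an MCMC fit
#'
#' @param x A `spiral_draws` or `lcm_draws` tibble.
#' @param ... Unused.
#' @return A one-row tibble: draw counts, chain settings, seed and (for
#'   spiral fits) the minimum and maximum Metropolis acceptance rates.
#' @method glance spiral_draws
#' @export
glance.spiral_draws <- function(x, ...) {
  acc <- attr(x, "acceptance")
  tibble::tibble(n_draws = nrow(x), n_iter = attr(x, "n_iter"),
                 burn_in = attr(x, "burn_in"), thin = attr(x, "thin"),
                 seed = attr(x, "seed"),
                 min_accept = suppressWarnings(min(acc, na.rm = TRUE)),
                 max_accept = suppressWarnings(max(acc, na.rm = TRUE)))
}

#' @rdname glance.spiral_draws
#' @method glance lcm_draws
#' @export
glance.lcm_draws <- function(x, ...) {
  tibble::tibble(n_draws = nrow(x), n_iter = attr(x, "n_iter"),
                 burn_in = attr(x, "burn_in"), thin = attr(x, "thin"),
                 seed = attr(x, "seed"))
}

#' @rdname tidy.spiral_draws
#' @method tidy lcm_ml
#' @export
tidy.lcm_ml <- function(x, ...) {
  dplyr::rename(x$estimates, std.error = "se")
}

#' @rdname glance.spiral_draws
#' @method glance lcm_ml
#' @export
glance.lcm_ml <- function(x, ...) {
  vc <- tidyr::pivot_wider(x$varcomp, names_from = "component",
                           values_from = "variance")
  dplyr::bind_cols(tibble::tibble(REML_criterion = lme4::REMLcrit(x$fit)),
                   vc)
}

#' @rdname tidy.spiral_draws
#' @method tidy spiral_report
#' @export
tidy.spiral_report <- function(x, ...) {
  x$individuals
}
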