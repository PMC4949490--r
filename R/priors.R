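# Empirical-Bayes hyperprior construction from per-individual OLS fits,
# plus the fixed prior constants of the hierarchical model.

#' Per-individual ordinary least-squares fits
#'
#' Fits `score ~ trial` separately for each individual (the maximum
#' likelihood estimate under normal errors). These per-individual estimates
#' feed the empirical-Bayes hyperprior recipe.
#'
#' @param cohort A cohort tibble.
#' @return Tibble: `individual`, `group`, `intercept`, `slope`, `resid_var`
#'   (residual variance with denominator `T - 2`).
#' @export
per_individual_ols <- function(cohort) {
  d <- cohort_dims(cohort)
  if (d$T < 3) stop("need at least 3 trials per individual", call. = FALSE)
  y <- cohort_matrix(cohort)
  X <- cbind(1, seq_len(d$T))
  coefs <- y %*% X %*% solve(crossprod(X))    # J x 2, normal equations
  resid <- y - coefs %*% t(X)
  tibble::tibble(individual = d$ids,
                 group = unname(d$group[d$ids]),
                 intercept = unname(coefs[, 1]),
                 slope = unname(coefs[, 2]),
                 resid_var = unname(rowSums(resid^2)) / (d$T - 2))
}

#' Empirical-Bayes hyperprior construction
#'
#' Hyperpriors for the population means are normal, centered at the average
#' of the per-individual OLS estimates with standard deviation equal to half
#' the range of those estimates. For the spiral model the pre-spiral
#' slope-mean hyperprior (both group components) is centered at the mean of
#' the positive OLS slopes (falling back to the absolute overall mean when
#' no slope is positive) and the post-spiral slope-mean hyperprior at the
#' negated value, each with sd = half the OLS-slope range. The observation
#' variance prior is IG(a = 2.5, b) with b chosen so the prior mean equals
#' the pooled OLS residual variance; the coefficient-variance priors are
#' IG(2, scale) with scale matched to the empirical variance of the OLS
#' coefficients. Degenerate (zero) ranges are floored at `sd_floor` with a
#' warning.
#'
#' @param cohort A cohort tibble.
#' @param c_delta Prior variance of the logistic spiral-propensity
#'   coefficients (`delta ~ N(0, c_delta I_2)`); the default 4 corresponds
#'   approximately to a joint uniform prior on the spiral probabilities.
#' @param a_sigma Shape of the IG prior on the observation variance.
#' @param sd_floor Minimum hyperprior sd (score units).
#' @return A list of class `spiral_priors`; see Details for fields.
#' @details Fields: `mu_alpha = c(center, sd)`; `mu_beta` (baseline-model
#'   slope-mean hyperprior), `mu_beta1`, `mu_beta2` likewise; `sigma2 =
#'   c(shape, scale)`; `tau_alpha2`, `tau_beta2_lcm`, `tau_beta1_sq`,
#'   `tau_beta2_sq` IG `c(shape, scale)` pairs; `c_delta`.
#' @export
empirical_bayes_priors <- function(cohort, c_delta = 4, a_sigma = 2.5,
                                   sd_floor = 1e-3) {
  ols <- per_individual_ols(cohort)
  if (nrow(ols) < 2) stop("need at least 2 individuals", call. = FALSE)
  half_range <- function(x) (max(x) - min(x)) / 2
  guard <- function(s, what) {
    if (s < sd_floor) {
      warning("hyperprior sd for ", what, " floored at ", sd_floor,
              call. = FALSE)
      sd_floor
    } else s
  }
  sd_a <- guard(half_range(ols$intercept), "mu_alpha")
  sd_b <- guard(half_range(ols$slope), "slope means")
  pos <- ols$slope[ols$slope > 0]
  center_b1 <- if (length(pos) > 0) mean(pos) else abs(mean(ols$slope))
  pooled_rv <- max(mean(ols$resid_var), sd_floor^2)
  var_int <- max(stats::var(ols$intercept), sd_floor^2)
  var_slope <- max(stats::var(ols$slope), sd_floor^2)
  out <- list(
    mu_alpha = c(center = mean(ols$intercept), sd = sd_a),
    mu_beta = c(center = mean(ols$slope), sd = sd_b),
    mu_beta1 = c(center = center_b1, sd = sd_b),
    mu_beta2 = c(center = -center_b1, sd = sd_b),
    sigma2 = c(shape = a_sigma, scale = (a_sigma - 1) * pooled_rv),
    tau_alpha2 = c(shape = 2, scale = var_int),
    tau_beta2_lcm = c(shape = 2, scale = var_slope),
    tau_beta1_sq = c(shape = 2, scale = var_slope),
    tau_beta2_sq = c(shape = 2, scale = var_slope),
    c_delta = c_delta,
    sd_floor = sd_floor
  )
  class(out) <- "spiral_priors"
  out
}

#' @export
print.spiral_priors <- function(x, ...) {
  cat("Hyperprior configuration (spiral_priors)\n")
  fmt <- function(v) paste(sprintf("%s=%.4g", names(v), v), collapse = ", ")
  for (nm in c("mu_alpha", "mu_beta", "mu_beta1", "mu_beta2")) {
    cat(sprintf("  %-13s normal(%s)\n", nm, fmt(x[[nm]])))
  }
  for (nm in c("sigma2", "tau_alpha2", "tau_beta2_lcm",
               "tau_beta1_sq", "tau_beta2_sq")) {
    cat(sprintf("  %-13s inv-gamma(%s)\n", nm, fmt(x[[nm]])))
  }
  cat(sprintf("  c_delta       %.4g\n", x$c_delta))
  invisible(x)
}

#' Serialize / restore a prior configuration
#'
#' @param priors A `spiral_priors` object.
#' @param path YAML file path.
#' @export
write_priors <- function(priors, path) {
  yaml::write_yaml(lapply(unclass(priors), as.list), path)
  invisible(path)
}

#' @rdname write_priors
#' @export
read_priors <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(v) unlist(v))
  class(out) <- "spiral_priors"
  out
}
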