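#' Weakly informative prior settings
#'
#' Default priors for every parameter of the hierarchy, written as
#' N(mean, variance) for Gaussian priors:
#' \itemize{
#'   \item `alpha` (mean of the individual random effects): N(0, 1000)
#'   \item `1/rho2` (precision of the individual effects): Gamma(1, 1)
#'   \item `psi` (scale of the cyclic hour covariance): Gamma(1, 1)
#'   \item `nu` (correlation decay/hour): Uniform(3/24, 3/1), so the practical
#'     range 3/nu of the hour correlation lies between 1 and 24 hours
#'   \item sex/season fixed effects (`mu`, `gamma`, `xi`): N(0, 1000)
#'   \item anthropogenic multipliers `beta`: N(0, 1000)
#'   \item anthropogenic decays `phi`: Uniform(3/4, 3/0.2), i.e. a practical
#'     range between 0.2 and 4 km
#'   \item `1/sigma2` (residual precision): Gamma(1, 1)
#' }
#'
#' @param ... named overrides of any listed component.
#' @return object of class `diel_priors`.
#' @export
diel_priors <- function(...) {
  p <- list(
    alpha_mean = 0, alpha_var = 1000,
    rho2_shape = 1, rho2_rate = 1,
    psi_shape = 1, psi_rate = 1,
    nu_low = 3 / 24, nu_high = 3,
    fixed_var = 1000,
    beta_var = 1000,
    phi_low = 3 / 4, phi_high = 3 / 0.2,
    sigma2_shape = 1, sigma2_rate = 1
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown prior component(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  with(p, {
    if (alpha_var <= 0 || fixed_var <= 0 || beta_var <= 0 ||
        rho2_shape <= 0 || rho2_rate <= 0 || psi_shape <= 0 || psi_rate <= 0 ||
        sigma2_shape <= 0 || sigma2_rate <= 0) {
      stop("prior variances, shapes and rates must be > 0")
    }
    if (nu_low >= nu_high || nu_low <= 0) stop("nu prior bounds must satisfy 0 < low < high")
    if (phi_low >= phi_high || phi_low <= 0) stop("phi prior bounds must satisfy 0 < low < high")
  })
  structure(p, class = "diel_priors")
}

#' Joint log prior density of a parameter state
#'
#' Sum of the log prior densities of every parameter a model uses: the
#' multivariate-normal MN(0, Sigma(nu, psi)) prior of each hour-effect
#' vector, Gaussian priors on `alpha` and the fixed and `beta` coefficients,
#' Gamma priors on the precisions `1/rho2`, `1/sigma2` and on `psi`, and
#' uniform priors on `nu` and each `phi`. Returns `-Inf` outside the uniform
#' supports or for non-positive variance parameters.
#'
#' @param state parameter state as returned by [diel_state()].
#' @param priors a [diel_priors()].
#' @param spec a [model_spec()].
#' @return scalar log density.
#' @export
log_prior <- function(state, priors, spec) {
  stopifnot(inherits(priors, "diel_priors"), inherits(spec, "model_spec"))
  if (state$nu < priors$nu_low || state$nu > priors$nu_high) return(-Inf)
  if (length(state$phi) && (any(state$phi < priors$phi_low) ||
                            any(state$phi > priors$phi_high))) return(-Inf)
  if (state$psi <= 0 || state$sigma2 <= 0 || state$rho2 <= 0) return(-Inf)

  lp <- stats::dunif(state$nu, priors$nu_low, priors$nu_high, log = TRUE)
  if (length(state$phi)) {
    lp <- lp + sum(stats::dunif(state$phi, priors$phi_low, priors$phi_high,
                                log = TRUE))
  }
  # precisions 1/rho2, 1/sigma2 and the scale psi carry Gamma priors
  lp <- lp + stats::dgamma(1 / state$rho2, priors$rho2_shape, priors$rho2_rate,
                           log = TRUE)
  lp <- lp + stats::dgamma(1 / state$sigma2, priors$sigma2_shape,
                           priors$sigma2_rate, log = TRUE)
  lp <- lp + stats::dgamma(state$psi, priors$psi_shape, priors$psi_rate,
                           log = TRUE)
  lp <- lp + stats::dnorm(state$alpha, priors$alpha_mean,
                          sqrt(priors$alpha_var), log = TRUE)
  if (length(state$fixed)) {
    lp <- lp + sum(stats::dnorm(state$fixed, 0, sqrt(priors$fixed_var),
                                log = TRUE))
  }
  if (length(state$beta)) {
    lp <- lp + sum(stats::dnorm(state$beta, 0, sqrt(priors$beta_var),
                                log = TRUE))
  }
  # individual effects omega_k ~ N(alpha, rho2)
  if (length(state$omega)) {
    lp <- lp + sum(stats::dnorm(state$omega, state$alpha, sqrt(state$rho2),
                                log = TRUE))
  }
  # hour-effect vectors ~ MN(0, Sigma(nu, psi)), shared (nu, psi)
  cv <- hour_covariance(state$nu, state$psi)
  Q <- hour_covariance_inverse(cv)
  ld <- sum(log(hour_covariance_eigenvalues(cv)))
  for (c in seq_len(ncol(state$lambda))) {
    v <- state$lambda[, c]
    lp <- lp - 0.5 * (24 * log(2 * pi) + ld + drop(v %*% Q %*% v))
  }
  lp
}
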