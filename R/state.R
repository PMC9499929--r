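#' Construct a full parameter state for a model
#'
#' A parameter state holds one value of every parameter a model uses:
#' the hour-effect vectors (24 rows, one column per stratum), individual
#' effects `omega`, their mean `alpha` and variance `rho2`, the free fixed
#' sex/season coefficients, the anthropogenic `beta`/`phi` pairs, the hour
#' covariance parameters `nu`/`psi`, and the residual variance `sigma2`.
#' Unsupplied components default to zero effects and unit variances, with
#' `nu` and `phi` at their prior midpoints.
#'
#' @param spec a [model_spec()].
#' @param n_animals number of individuals (length of `omega`).
#' @param priors a [diel_priors()] (for the uniform midpoints).
#' @param ... named components to set (`lambda`, `omega`, `alpha`, `rho2`,
#'   `fixed`, `beta`, `phi`, `nu`, `psi`, `sigma2`).
#' @return object of class `diel_state`.
#' @export
diel_state <- function(spec, n_animals = 0L, priors = diel_priors(), ...) {
  stopifnot(inherits(spec, "model_spec"))
  strata <- lambda_strata(spec)
  fx <- fixed_coef_names(spec)
  bn <- anthro_coef_names(spec, "beta")
  pn <- anthro_coef_names(spec, "phi")
  st <- list(
    lambda = matrix(0, 24, nrow(strata), dimnames = list(NULL, strata$label)),
    omega = stats::setNames(numeric(n_animals), if (n_animals) paste0("b", seq_len(n_animals))),
    alpha = 0, rho2 = 1,
    fixed = stats::setNames(numeric(length(fx)), fx),
    beta = stats::setNames(numeric(length(bn)), bn),
    phi = stats::setNames(rep((priors$phi_low + priors$phi_high) / 2,
                              length(pn)), pn),
    nu = (priors$nu_low + priors$nu_high) / 2,
    psi = 1, sigma2 = 1
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(st))
  if (length(bad)) stop("unknown state component(s): ", paste(bad, collapse = ", "))
  for (nm in names(ov)) {
    v <- ov[[nm]]
    if (nm == "lambda") {
      v <- as.matrix(v)
      if (!all(dim(v) == dim(st$lambda))) stop("lambda must be 24 x ", ncol(st$lambda))
      dimnames(v) <- dimnames(st$lambda)
    } else if (length(v) != length(st[[nm]]) && length(v) == 1L &&
               nm %in% c("omega", "fixed", "beta", "phi")) {
      v <- rep(v, length(st[[nm]]))
    }
    if (nm != "lambda" && length(v) != length(st[[nm]])) {
      stop(sprintf("component '%s' must have length %d", nm, length(st[[nm]])))
    }
    if (nm != "lambda") names(v) <- names(st[[nm]])
    st[[nm]] <- v
  }
  st$spec <- spec
  structure(st, class = "diel_state")
}

#' Exponential distance-decay effect
#'
#' The anthropogenic effect of a feature at distance `x_km`:
#' `beta * exp(-phi * x_km)`. Equals `beta` on the feature and decays to a
#' negligible value beyond the practical range `3/phi` km.
#'
#' @param beta effect multiplier at distance zero (sqrt km/h scale).
#' @param phi decay per km (> 0).
#' @param x_km distance in km (>= 0), vectorised.
#' @return numeric vector of effects.
#' @export
anthropogenic_effect <- function(beta, phi, x_km) {
  if (any(!is.finite(phi)) || any(phi <= 0)) stop("phi must be > 0")
  if (any(!is.finite(x_km)) || any(x_km < 0)) stop("distances must be >= 0")
  beta * exp(-phi * x_km)
}

#' Linear predictor of the movement-rate model
#'
#' Assembles, for every observation, the model's linear predictor on the
#' square-root scale: the hour effect of the observation's stratum, the
#' individual effect, the fixed sex/season terms, and the exponential
#' distance-decay terms of the model's anthropogenic block.
#'
#' @param state a [diel_state()] dimensioned for `spec`.
#' @param records observation data frame with columns `hour_index`, `season`,
#'   `sex` (1 = F, 2 = M or "F"/"M"), `animal` (integer index into
#'   `state$omega`) and the distance columns `x1`..`x4` the model needs.
#' @param spec a [model_spec()].
#' @return numeric vector, one predictor value per record.
#' @export
linear_predictor <- function(state, records, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!identical(state$spec$id, spec$id)) stop("state was built for model ", state$spec$id)
  sex <- records$sex
  if (!is.numeric(sex)) sex <- match(as.character(sex), SEX_CODES)
  season <- as.integer(records$season)
  hour <- as.integer(records$hour_index)
  if (any(hour < 1L | hour > 24L)) stop("hour_index out of 1..24")

  strat <- lambda_stratum_of(spec, season, sex)
  eta <- state$lambda[cbind(hour, strat)]
  if (length(state$omega)) {
    k <- as.integer(records$animal)
    if (any(is.na(k)) || any(k < 1L | k > length(state$omega))) {
      stop("records$animal must index state$omega")
    }
    eta <- eta + state$omega[k]
  }
  fd <- fixed_design(spec, season, sex)
  for (col in seq_len(ncol(fd))) {
    idx <- fd[, col]
    hit <- idx > 0L
    eta[hit] <- eta[hit] + state$fixed[idx[hit]]
  }
  if (spec$anthro != "none") {
    for (jpos in seq_along(spec$features)) {
      j <- spec$features[jpos]
      x <- records[[paste0("x", j)]]
      if (is.null(x)) stop("records lack distance column x", j)
      if (spec$by_season) {
        off <- (jpos - 1L) * 4L
        b <- state$beta[off + season]
        p <- state$phi[off + season]
      } else {
        b <- state$beta[jpos]
        p <- state$phi[jpos]
      }
      eta <- eta + anthropogenic_effect(b, p, x)
    }
  }
  unname(eta)
}

#' Gaussian log likelihood of the observations
#'
#' Sum over records of the log normal density of the square-root movement
#' rate `y` around the linear predictor, with residual variance `sigma2`.
#'
#' @inheritParams linear_predictor
#' @return scalar log likelihood.
#' @export
log_likelihood <- function(state, records, spec) {
  if (state$sigma2 <= 0) stop("sigma2 must be > 0")
  if (nrow(records) == 0L) return(0)
  mu <- linear_predictor(state, records, spec)
  sum(stats::dnorm(records$y, mu, sqrt(state$sigma2), log = TRUE))
}
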