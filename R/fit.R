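#' MCMC run settings
#'
#' Chain protocol for [diel_fit()]. The default profile mirrors the study
#' protocol: two chains, 50,000 burn-in iterations, 20,000 further
#' iterations thinned by 10, i.e. 2,000 retained draws per chain.
#' `profile = "desk"` switches to a light profile (burn 2,000 / keep 2,000 /
#' thin 2) for interactive work and simulation studies.
#'
#' @param n_chains number of chains (>= 1; >= 2 for convergence checks).
#' @param burn_in burn-in iterations.
#' @param keep_iters post-burn-in iterations.
#' @param thin thinning interval; `keep_iters` must be divisible by it.
#' @param seed integer seed; all chain randomness derives from it.
#' @param adapt_during_burnin adapt Metropolis step sizes during burn-in
#'   (adaptation is always frozen afterwards).
#' @param profile `"paper"` (default) or `"desk"`.
#' @return object of class `diel_control`.
#' @export
diel_control <- function(n_chains = 2L, burn_in = 50000L, keep_iters = 20000L,
                         thin = 10L, seed = 1L, adapt_during_burnin = TRUE,
                         profile = c("paper", "desk")) {
  profile <- match.arg(profile)
  if (profile == "desk") {
    if (missing(burn_in)) burn_in <- 2000L
    if (missing(keep_iters)) keep_iters <- 2000L
    if (missing(thin)) thin <- 2L
  }
  if (burn_in < 0 || keep_iters <= 0 || thin <= 0) stop("invalid iteration counts")
  if (keep_iters %% thin != 0) stop("keep_iters must be divisible by thin")
  if (n_chains < 1) stop("need at least one chain")
  structure(list(n_chains = as.integer(n_chains), burn_in = as.integer(burn_in),
                 keep_iters = as.integer(keep_iters), thin = as.integer(thin),
                 seed = as.integer(seed),
                 adapt_during_burnin = isTRUE(adapt_during_burnin),
                 profile = profile),
            class = "diel_control")
}

# Column layout of the draw matrix for a model: names and index helpers,
# in the sampler's storage order.
param_layout <- function(spec, animal_ids) {
  strata <- lambda_strata(spec)
  K <- length(animal_ids)
  lam <- as.vector(vapply(strata$label, function(l)
    sprintf("lambda_%s_h%02d", l, 1:24), character(24)))
  fx <- fixed_coef_names(spec)
  bn <- anthro_coef_names(spec, "beta")
  pn <- anthro_coef_names(spec, "phi")
  nm <- c(lam, if (K) paste0("omega_", animal_ids), "alpha", "rho2",
          fx, bn, pn, "nu", "psi", "sigma2")
  list(names = nm, n_strata = nrow(strata), strata = strata, K = K,
       lam_end = 24L * nrow(strata),
       omega_at = 24L * nrow(strata),
       alpha_col = 24L * nrow(strata) + K + 1L,
       fixed_at = 24L * nrow(strata) + K + 2L,
       nfix = length(fx),
       beta_at = 24L * nrow(strata) + K + 2L + length(fx),
       totG = length(bn),
       phi_at = 24L * nrow(strata) + K + 2L + length(fx) + length(bn),
       sigma2_col = length(nm))
}

# Assemble the sampler's data arrays from an observation table.
prepare_model_data <- function(records, spec) {
  if (nrow(records) > 0L && !all(c("y", "hour_index", "season") %in% names(records))) {
    stop("records must carry columns y, hour_index, season")
  }
  sex <- records$sex
  if (!is.numeric(sex)) sex <- match(as.character(sex), SEX_CODES)
  season <- as.integer(records$season)
  hour <- as.integer(records$hour_index)
  if (nrow(records) > 0L) {
    if (any(is.na(sex))) stop("sex must be 'F'/'M' (or 1/2)")
    if (any(is.na(season) | season < 1L | season > 4L)) stop("season out of 1..4")
    if (any(is.na(hour) | hour < 1L | hour > 24L)) stop("hour_index out of 1..24")
  }
  animal_ids <- unique(as.character(records$animal_id))
  animal <- match(as.character(records$animal_id), animal_ids)
  strat <- lambda_stratum_of(spec, season, sex)
  fixmap <- fixed_design(spec, season, sex)
  storage.mode(fixmap) <- "integer"
  J <- length(spec$features)
  X <- matrix(0, nrow(records), J)
  agrp <- matrix(1L, nrow(records), J)
  for (jpos in seq_along(spec$features)) {
    x <- records[[paste0("x", spec$features[jpos])]]
    if (is.null(x) || any(!is.finite(x)) || any(x < 0)) {
      stop("model ", spec$id, " needs finite non-negative distance column x",
           spec$features[jpos])
    }
    X[, jpos] <- x
    if (spec$by_season) agrp[, jpos] <- season
  }
  ngrp <- rep(if (spec$by_season) 4L else 1L, J)
  list(y = as.numeric(records$y), hour = hour, strat = as.integer(strat),
       season = season, sex = as.integer(sex),
       animal = as.integer(animal), animal_ids = animal_ids,
       fixmap = fixmap, X = X, agrp = agrp, ngrp = as.integer(ngrp))
}

#' Fit a circadian movement-rate model
#'
#' Fits one of the thirteen registry models to an observation table by
#' Metropolis-within-Gibbs sampling. All Gaussian location blocks (the
#' 24-hour effect vectors jointly per stratum, individual effects, fixed
#' sex/season terms and the anthropogenic multipliers given their decays)
#' are conjugate Gibbs updates, as are the residual and individual-effect
#' precisions and the hour-covariance scale `psi`; the covariance decay `nu`
#' and each distance decay `phi` use adaptive reflected random-walk
#' Metropolis, with adaptation frozen after burn-in. Identical seeds give
#' bit-identical chains.
#'
#' @param records observation table ([build_observations()] schema, or the
#'   records of [simulate_records()]); may have zero rows for a
#'   prior-only run (supply `n_animals = 0` data implicitly).
#' @param model model id 1..13 or a [model_spec()].
#' @param priors a [diel_priors()].
#' @param control a [diel_control()].
#' @param fix optional named list fixing any of `nu`, `psi`, `sigma2`,
#'   `rho2` at a constant (update skipped).
#' @return object of class `diel_fit`: pooled thinned draws (`$draws`, one
#'   column per scalar parameter, with `$chain` giving each row's chain),
#'   per-chain Metropolis acceptance rates, the model spec, priors, control
#'   and prepared data.
#' @examples
#' sim <- simulate_study(model = 1, n_bears = 4, study_days = 10, seed = 1)
#' fit <- diel_fit(sim$records, model = 1,
#'                 control = diel_control(profile = "desk", n_chains = 1,
#'                                        burn_in = 200, keep_iters = 200,
#'                                        thin = 1, seed = 1))
#' print(fit)
#' @export
diel_fit <- function(records, model = 1L, priors = diel_priors(),
                     control = diel_control(), fix = list()) {
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  stopifnot(inherits(priors, "diel_priors"), inherits(control, "diel_control"))
  bad <- setdiff(names(fix), c("nu", "psi", "sigma2", "rho2"))
  if (length(bad)) stop("cannot fix parameter(s): ", paste(bad, collapse = ", "))
  md <- prepare_model_data(records, spec)
  lay <- param_layout(spec, md$animal_ids)

  init_lp_check(md, spec, priors, fix)

  set.seed(control$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, control$n_chains)
  n_out <- control$keep_iters %/% control$thin
  draws <- matrix(NA_real_, n_out * control$n_chains, length(lay$names),
                  dimnames = list(NULL, lay$names))
  chain <- integer(0)
  accept <- NULL
  for (ch in seq_len(control$n_chains)) {
    set.seed(chain_seeds[ch])
    out <- run_chain_cpp(md$y, md$hour, md$strat, lay$n_strata, md$animal,
                         lay$K, md$fixmap, lay$nfix, md$X, md$agrp, md$ngrp,
                         unclass(priors), fix, control$burn_in,
                         control$keep_iters, control$thin,
                         control$adapt_during_burnin)
    rows <- (ch - 1L) * n_out + seq_len(n_out)
    draws[rows, ] <- out$draws
    chain <- c(chain, rep.int(ch, n_out))
    accept <- rbind(accept, out$accept)
  }
  colnames(accept) <- c("nu", anthro_coef_names(spec, "phi"))
  structure(list(draws = draws, chain = chain, accept = accept, spec = spec,
                 priors = priors, control = control, fix = fix,
                 data = records, model_data = md, layout = lay),
            class = "diel_fit")
}

# Fail early, and by name, if the posterior is non-finite at initialization.
init_lp_check <- function(md, spec, priors, fix) {
  n <- length(md$y)
  if (n == 0L) return(invisible())
  if (any(!is.finite(md$y))) stop("non-finite response y at initialization")
  for (nm in names(fix)) {
    v <- fix[[nm]]
    if (!is.numeric(v) || !is.finite(v) || v <= 0) {
      stop("fixed value for ", nm, " makes the posterior non-finite")
    }
  }
  if (!is.null(fix$nu) && (fix$nu < priors$nu_low || fix$nu > priors$nu_high)) {
    stop("fixed nu lies outside its uniform prior support")
  }
  invisible()
}

#' Pooled posterior draws of a fit
#'
#' @param x a `diel_fit`.
#' @param ... unused.
#' @return numeric matrix, one column per scalar parameter.
#' @export
as.matrix.diel_fit <- function(x, ...) x$draws

#' @export
print.diel_fit <- function(x, ...) {
  cat(sprintf("Circadian movement-rate model %d: y = %s + eps\n",
              x$spec$id, render_formula(x$spec)))
  cat(sprintf("  %d observations, %d animals; %d chain(s) x %d draws (burn %d, thin %d)\n",
              nrow(x$data), x$layout$K, x$control$n_chains,
              x$control$keep_iters %/% x$control$thin, x$control$burn_in,
              x$control$thin))
  key <- intersect(c("alpha", "sigma2", "nu", "psi", "rho2"),
                   colnames(x$draws))
  ps <- posterior_summary(x, key)
  ps[-1] <- round(ps[-1], 3)
  print(ps)
  invisible(x)
}

#' @export
summary.diel_fit <- function(object, pars = NULL, ...) {
  out <- posterior_summary(object, pars)
  if (object$control$n_chains >= 2L) {
    out$psrf <- vapply(out$parameter, function(p) gelman_rubin(object, p),
                       numeric(1))
  }
  out
}

#' @export
coef.diel_fit <- function(object, ...) colMeans(object$draws)

# Rebuild a full diel_state from one draw (or the posterior mean).
state_from_draw <- function(fit, draw) {
  lay <- fit$layout
  spec <- fit$spec
  v <- if (is.matrix(draw)) draw[1L, ] else draw
  lam <- matrix(v[seq_len(lay$lam_end)], 24, lay$n_strata)
  colnames(lam) <- lay$strata$label
  diel_state(spec, n_animals = lay$K, priors = fit$priors,
             lambda = lam,
             omega = if (lay$K) unname(v[lay$omega_at + seq_len(lay$K)]) else numeric(0),
             alpha = unname(v[lay$alpha_col]),
             rho2 = unname(v[lay$alpha_col + 1L]),
             fixed = if (lay$nfix) unname(v[lay$fixed_at + seq_len(lay$nfix)]) else numeric(0),
             beta = if (lay$totG) unname(v[lay$beta_at + seq_len(lay$totG)]) else numeric(0),
             phi = if (lay$totG) unname(v[lay$phi_at + seq_len(lay$totG)]) else numeric(0),
             nu = unname(v["nu"]), psi = unname(v["psi"]),
             sigma2 = unname(v["sigma2"]))
}

#' @export
predict.diel_fit <- function(object, newdata = NULL,
                             type = c("sqrt", "rate"), ...) {
  type <- match.arg(type)
  recs <- if (is.null(newdata)) object$data else newdata
  recs$animal <- match(as.character(recs$animal_id),
                       object$model_data$animal_ids)
  st <- state_from_draw(object, colMeans(object$draws))
  eta <- linear_predictor(st, recs, object$spec)
  if (type == "rate") pmax(eta, 0)^2 else eta
}

#' @export
fitted.diel_fit <- function(object, ...) predict(object)

#' @export
residuals.diel_fit <- function(object, ...) object$data$y - predict(object)

#' @export
simulate.diel_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  recs <- object$data
  recs$animal <- match(as.character(recs$animal_id),
                       object$model_data$animal_ids)
  out <- vapply(idx, function(d) {
    st <- state_from_draw(object, object$draws[d, ])
    linear_predictor(st, recs, object$spec) +
      stats::rnorm(nrow(recs), 0, sqrt(st$sigma2))
  }, numeric(nrow(recs)))
  as.data.frame(out)
}

#' Posterior mean and 95% credibility interval
#'
#' Pooled across chains (post burn-in); the credibility interval is the
#' equal-tailed interval between the 2.5% and 97.5% posterior quantiles.
#' This is the single summarising routine every table and curve in the
#' package goes through.
#'
#' @param x a `diel_fit`, or a numeric matrix / vector of draws.
#' @param pars parameter names (default: all columns).
#' @param prob interval mass (default 0.95).
#' @return data frame `parameter, mean, sd, ci_low, ci_high`.
#' @export
posterior_summary <- function(x, pars = NULL, prob = 0.95) {
  draws <- if (inherits(x, "diel_fit")) x$draws else x
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1,
                                        dimnames = list(NULL, "x"))
  if (is.null(pars)) pars <- colnames(draws)
  a <- (1 - prob) / 2
  out <- data.frame(parameter = pars,
                    mean = colMeans(draws[, pars, drop = FALSE]),
                    sd = apply(draws[, pars, drop = FALSE], 2, stats::sd),
                    ci_low = apply(draws[, pars, drop = FALSE], 2,
                                   stats::quantile, probs = a),
                    ci_high = apply(draws[, pars, drop = FALSE], 2,
                                    stats::quantile, probs = 1 - a),
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF from two or more equal-length chains: the square root of
#' the ratio of the pooled-variance estimate to the mean within-chain
#' variance. Values near 1 indicate the chains agree.
#'
#' @param x a `diel_fit` with >= 2 chains, or a list of equal-length
#'   numeric vectors (one per chain).
#' @param parameter parameter name (when `x` is a fit).
#' @return scalar PSRF (>= 1 up to numerical noise).
#' @export
gelman_rubin <- function(x, parameter = NULL) {
  chains <- if (inherits(x, "diel_fit")) {
    if (is.null(parameter)) stop("give a parameter name")
    split(x$draws[, parameter], x$chain)
  } else x
  m <- length(chains)
  if (m < 2L) stop("need at least two chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length")
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  Vhat <- (n - 1) / n * W + (1 + 1 / m) * B / n
  sqrt(Vhat / W)
}
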