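# Shared fixtures and independent oracles, all built in code.

# A fix table on an hourly schedule for one or more animals.
make_fixes <- function(animal_id = "a1", sex = "F",
                       start = "2008-04-01 00:00:00", n = 24,
                       x = NULL, y = NULL, step_m = 300) {
  t0 <- as.POSIXct(start, tz = "UTC")
  if (is.null(x)) x <- 500000 + step_m * seq_len(n)
  if (is.null(y)) y <- rep(4600000, n)
  data.frame(animal_id = animal_id, sex = sex,
             timestamp = t0 + 3600 * (seq_len(n) - 1L),
             x = x, y = y, stringsAsFactors = FALSE)
}

# Observation rows with explicit fields (no simulation).
make_obs <- function(n = 48, seed = 1) {
  set.seed(seed)
  data.frame(
    animal_id = sample(c("a1", "a2"), n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE),
    timestamp = as.POSIXct("2008-04-01", tz = "UTC") + 3600 * seq_len(n),
    hour_index = sample(1:24, n, replace = TRUE),
    season = sample(1:4, n, replace = TRUE),
    rate_kmh = NA_real_,
    y = rnorm(n, 0.5, 0.2),
    x1 = NA_real_, x2 = exp(runif(n, log(0.02), log(4))),
    x3 = exp(runif(n, log(0.02), log(4))),
    x4 = exp(runif(n, log(0.02), log(4))),
    stringsAsFactors = FALSE)
}

# Minimal fitted-model stub whose draws the test controls directly.
make_stub_fit <- function(spec_id, draws, animal_ids = c("a1", "a2"),
                          chain = NULL) {
  spec <- model_spec(spec_id)
  lay <- bearcadian:::param_layout(spec, animal_ids)
  stopifnot(ncol(draws) == length(lay$names))
  colnames(draws) <- lay$names
  structure(list(draws = draws, chain = if (is.null(chain)) rep(1L, nrow(draws)) else chain,
                 accept = NULL, spec = spec, priors = diel_priors(),
                 control = diel_control(n_chains = 1, burn_in = 0,
                                        keep_iters = nrow(draws), thin = 1),
                 fix = list(), data = NULL, model_data = list(animal_ids = animal_ids),
                 layout = lay),
            class = "diel_fit")
}

# Draw matrix of zeros for a model, to be filled by name.
zero_draws <- function(spec_id, n_draws, animal_ids = c("a1", "a2")) {
  lay <- bearcadian:::param_layout(model_spec(spec_id), animal_ids)
  m <- matrix(0, n_draws, length(lay$names))
  colnames(m) <- lay$names
  # keep variance-like parameters valid
  m[, c("rho2", "psi", "sigma2")] <- 1
  m[, "nu"] <- 0.5
  phis <- grep("^phi_", lay$names, value = TRUE)
  if (length(phis)) m[, phis] <- 6
  m
}

# Brute-force point-to-segment distance via dense parameter grid.
oracle_segment_dist <- function(p, a, b, grid = 20001) {
  tt <- seq(0, 1, length.out = grid)
  px <- a[1] + tt * (b[1] - a[1])
  py <- a[2] + tt * (b[2] - a[2])
  min(sqrt((px - p[1])^2 + (py - p[2])^2))
}

# Sort-based type-7 quantile oracle.
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Independent evaluation of a model's linear predictor, term by term,
# written directly against the 13-model registry definitions.
oracle_predictor <- function(state, rec, spec) {
  sex <- if (is.numeric(rec$sex)) rec$sex else match(rec$sex, c("F", "M"))
  r <- rec$season; i <- rec$hour_index
  strat <- switch(spec$hour, hour = 1L, hour_season = r,
                  hour_season_sex = (sex - 1L) * 4L + r)
  eta <- state$lambda[i, strat] + state$omega[rec$animal]
  sc <- c("sp", "es", "ls", "fa")
  if (spec$fixed == "additive") {
    if (sex == 2L) eta <- eta + state$fixed[["mu_M"]]
    if (r > 1L) eta <- eta + state$fixed[[paste0("gamma_", sc[r])]]
  } else if (spec$fixed == "season") {
    if (r > 1L) eta <- eta + state$fixed[[paste0("gamma_", sc[r])]]
  } else if (spec$fixed == "interaction") {
    if (!(r == 1L && sex == 1L)) {
      eta <- eta + state$fixed[[paste0("xi_", sc[r], "_", c("F", "M")[sex])]]
    }
  }
  for (j in spec$features) {
    sfx <- if (spec$by_season) paste0("_", sc[r]) else ""
    b <- state$beta[[paste0("beta_x", j, sfx)]]
    ph <- state$phi[[paste0("phi_x", j, sfx)]]
    eta <- eta + b * exp(-ph * rec[[paste0("x", j)]])
  }
  unname(eta)
}

run_quiet <- function(expr) suppressMessages(suppressWarnings(expr))
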