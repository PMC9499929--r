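#' Simulate a typed landscape feature set
#'
#' Random primary/secondary road polylines and settlement points inside a
#' square study area, as a stand-in for real GIS layers. Reproducible by
#' seed and writable as GeoJSON via [write_features_geojson()]. All
#' coordinates are planar meters within the extent.
#'
#' @param extent_km side of the square study area (km).
#' @param n_primary,n_secondary,n_settlements feature counts (>= 0).
#' @param seed integer seed.
#' @return a `feature_set` (list of features with `ftype` and `coords`).
#' @export
simulate_landscape <- function(extent_km = 30, n_primary = 3,
                               n_secondary = 8, n_settlements = 5,
                               seed = 1L) {
  if (n_primary < 0 || n_secondary < 0 || n_settlements < 0) {
    stop("feature counts must be non-negative")
  }
  set.seed(seed)
  ext <- extent_km * 1000
  road <- function(ftype) {
    nv <- sample(3:6, 1)
    p <- matrix(NA_real_, nv, 2)
    p[1, ] <- stats::runif(2, 0, ext)
    ang <- stats::runif(1, 0, 2 * pi)
    for (i in 2:nv) {
      ang <- ang + stats::rnorm(1, 0, 0.5)
      step <- stats::runif(1, 0.15, 0.35) * ext
      p[i, ] <- pmin(pmax(p[i - 1, ] + step * c(cos(ang), sin(ang)), 0), ext)
    }
    list(ftype = ftype, coords = p)
  }
  feats <- c(lapply(seq_len(n_primary), function(i) road("primary_road")),
             lapply(seq_len(n_secondary), function(i) road("secondary_road")),
             lapply(seq_len(n_settlements), function(i) {
               list(ftype = "settlement",
                    coords = matrix(stats::runif(2, 0, ext), 1, 2))
             }))
  structure(feats, class = "feature_set", extent_m = ext)
}

#' Define the generating truth of a synthetic study
#'
#' Fixes every parameter of the generative model and the telemetry design
#' the generator emulates: hourly fixes over the March - mid-December
#' active period, a fix-acquisition probability, GPS location error, and a
#' collared sample of `n_bears` adults (`n_females` of them female). The
#' defaults are the study design of the source population: 18 bears
#' (11 F / 7 M), acquisition 0.88 (the middle of the observed 79-97%
#' range), mean location error 24.7 m, and a sqrt-scale predictor level
#' (`alpha` 0.55, hour-effect sd `1/sqrt(psi)` = 0.125, individual sd 0.1,
#' residual sd 0.29, decay `nu` 0.5) placing typical hourly rates in the
#' 0.15-0.5 km/h range while keeping the Gaussian model's negative-tail
#' truncation below ~5%. Hour-effect vectors are drawn from their
#' MN(0, Sigma(nu, psi)) prior unless supplied explicitly (see
#' [crepuscular_lambda()] for a bimodal template).
#'
#' @param model model id 1..13 or [model_spec()].
#' @param n_bears,n_females collared sample size and its female count.
#' @param study_days number of sampling days, spread evenly across the
#'   March 1 - December 15 active period (290 gives every day).
#' @param acquisition_rate per-hour probability a scheduled fix is
#'   acquired, in [0.79, 0.97].
#' @param gps_error_mean_m mean radial GPS location error (m).
#' @param seed integer seed (used for the lambda draw here and as the
#'   default generator seed).
#' @param lambda optional 24 x n_strata matrix of hour effects.
#' @param beta,phi,xi,mu,gamma,alpha,rho2,sigma2,nu,psi optional parameter
#'   overrides, in [diel_state()] layout for the model.
#' @param start_year calendar year of the study season.
#' @return object of class `synthetic_truth`.
#' @export
simulate_truth <- function(model = 9L, n_bears = 18L, n_females = 11L,
                           study_days = 290L, acquisition_rate = 0.88,
                           gps_error_mean_m = 24.7, seed = 1L,
                           lambda = NULL, beta = NULL, phi = NULL,
                           xi = NULL, mu = NULL, gamma = NULL,
                           alpha = 0.55, rho2 = 0.01, sigma2 = 0.29^2,
                           nu = 0.5, psi = 64, start_year = 2008L) {
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  if (n_females > n_bears || n_bears < 1L) stop("need 1 <= n_females <= n_bears")
  if (acquisition_rate < 0.79 || acquisition_rate > 0.97) {
    stop("acquisition_rate must lie in the observed 0.79-0.97 range")
  }
  priors <- diel_priors()
  set.seed(seed)
  strata <- lambda_strata(spec)
  if (is.null(lambda)) {
    cv <- hour_covariance(nu, psi)
    L <- chol(cv$Sigma)
    lambda <- vapply(seq_len(nrow(strata)),
                     function(c) drop(crossprod(L, stats::rnorm(24))),
                     numeric(24))
  }
  nb <- length(anthro_coef_names(spec, "beta"))
  if (is.null(beta)) {
    beta <- if (spec$id == 9L) {
      # paper-scale season-specific effects: x2, x3, x4 blocks
      c(0.337, 0.106, 0.084, 0.128,
        0.278, 0.131, 0.187, -0.042,
        0.440, -0.063, 0.272, -0.174)
    } else rep(0.25, nb)
  }
  if (is.null(phi)) phi <- rep(6, nb)
  fx <- fixed_coef_names(spec)
  fixed <- stats::setNames(numeric(length(fx)), fx)
  if (!is.null(mu)) fixed[grep("^mu_", fx)] <- mu
  if (!is.null(gamma)) fixed[grep("^gamma_", fx)] <- gamma
  if (!is.null(xi)) fixed[grep("^xi_", fx)] <- xi
  state <- diel_state(spec, n_animals = n_bears, priors = priors,
                      lambda = lambda,
                      omega = stats::rnorm(n_bears, alpha, sqrt(rho2)),
                      alpha = alpha, rho2 = rho2, fixed = fixed,
                      beta = beta, phi = phi, nu = nu, psi = psi,
                      sigma2 = sigma2)
  sexes <- rep(c("F", "M"), c(n_females, n_bears - n_females))
  structure(list(spec = spec, state = state, n_bears = as.integer(n_bears),
                 sexes = sexes, study_days = as.integer(study_days),
                 acquisition_rate = acquisition_rate,
                 gps_error_mean_m = gps_error_mean_m,
                 start_year = as.integer(start_year), seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' A crepuscular hour-effect template
#'
#' Bimodal hour-effect vector with Gaussian-shaped peaks at the given hours
#' (in circular distance), for injecting a known dawn/dusk activity pattern
#' into a synthetic truth. The template is roughly zero-mean — the overall
#' level is carried by `alpha` — so it is a plausible draw of the
#' MN(0, Sigma) hour effect.
#'
#' @param peak_hours hour indices of the peaks.
#' @param base sqrt-rate offset between peaks (negative: troughs sit below
#'   the population level `alpha`).
#' @param peak added sqrt-rate at each peak.
#' @param width peak width (hours).
#' @return numeric 24-vector.
#' @export
crepuscular_lambda <- function(peak_hours = c(5, 19), base = -0.12,
                               peak = 0.3, width = 1.5) {
  v <- rep(base, 24)
  for (p in peak_hours) {
    d <- circ_hour_dist(1:24, rep(p, 24))
    v <- v + peak * exp(-0.5 * (d / width)^2)
  }
  v
}

# Calendar days of the sampling schedule: study_days days spread evenly
# over March 1 - December 15 of the study year.
schedule_days <- function(truth) {
  d0 <- as.Date(sprintf("%d-03-01", truth$start_year))
  d1 <- as.Date(sprintf("%d-12-15", truth$start_year))
  span <- as.integer(d1 - d0)
  off <- unique(round(seq(0, span, length.out = min(truth$study_days, span + 1L))))
  d0 + off
}

#' Simulate movement records (and optionally GPS fixes) from a truth
#'
#' Draws the observation process of the generative model: for every bear
#' and scheduled hour, the sqrt-rate `y = lambda* + eps` with
#' `eps ~ N(0, sigma2)`, truncated at zero (the truncated fraction is
#' reported and warned about above 5%), and `rate = y^2`. Distance
#' covariates are simulated directly (log-uniform on 0.02-4 km) unless a
#' landscape is given, in which case each bear performs a random-heading
#' walk whose hourly step equals its movement rate, covariates are the
#' distances at the step's origin, and the walk's positions are emitted as
#' fixes (thinned by the acquisition rate, with GPS error applied). A
#' record requires both endpoint fixes of its hour to be acquired.
#'
#' @param truth a [simulate_truth()].
#' @param landscape optional `feature_set`.
#' @param seed integer seed (defaults to the truth's).
#' @return list with `records` (observation-table schema), `fixes`
#'   (data frame, or `NULL` without a landscape), `truth`, and
#'   `truncation_rate`.
#' @export
simulate_records <- function(truth, landscape = NULL, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  spec <- truth$spec
  state <- truth$state
  set.seed(seed)
  # each sampling day schedules 25 hourly slots (00:00 through the closing
  # midnight), so the 23:00 -> 24:00 step is observable; overlapping
  # midnights of adjacent days collapse to one slot
  slot_times <- sort(unique(as.vector(outer(
    as.numeric(as.POSIXct(paste(schedule_days(truth), "00:00:00"), tz = "UTC")),
    3600 * (0:24), "+"))))
  base <- expand.grid(time = slot_times, bear = seq_len(truth$n_bears))
  ts <- as.POSIXct(base$time, tz = "UTC", origin = "1970-01-01")
  df <- data.frame(animal_id = sprintf("bear%02d", base$bear),
                   sex = truth$sexes[base$bear],
                   timestamp = ts, stringsAsFactors = FALSE)
  df$hour_index <- hour_index(df$timestamp)
  df$season <- season_of(df$timestamp)
  keep_row <- !is.na(df$season)
  df <- df[keep_row, ]
  df$animal <- base$bear[keep_row]
  n <- nrow(df)
  acquired <- stats::runif(n) < truth$acquisition_rate

  fixes <- NULL
  if (is.null(landscape)) {
    lx <- function() exp(stats::runif(n, log(0.02), log(4)))
    df$x2 <- lx(); df$x3 <- lx(); df$x4 <- lx()
    df$x1 <- pmin(df$x2, df$x3)
    mu <- linear_predictor(state, df, spec)
    yr <- mu + stats::rnorm(n, 0, sqrt(state$sigma2))
    trunc_rate <- mean(yr < 0)
    y <- pmax(yr, 0)
    df$rate_kmh <- y^2
    df$y <- y
    # a record needs its own and the following hour's fix acquired
    keep <- acquired
    nxt <- c(acquired[-1L], FALSE)
    same_series <- c(df$animal[-1L] == df$animal[-n] &
                       diff(as.numeric(df$timestamp)) == 3600, FALSE)
    keep <- keep & nxt & same_series
    records <- df[keep, ]
  } else {
    ext <- attr(landscape, "extent_m")
    if (is.null(ext)) {
      ext <- max(vapply(landscape, function(f) max(f$coords), numeric(1)))
    }
    df$x <- NA_real_; df$y_m <- NA_real_
    df$x1 <- df$x2 <- df$x3 <- df$x4 <- NA_real_
    yobs <- numeric(n); ntrunc <- 0L
    cols <- c("hour_index", "season", "sex", "animal", "x1", "x2", "x3", "x4")
    for (k in seq_len(truth$n_bears)) {
      ii <- which(df$animal == k)
      pos <- stats::runif(2, 0.25 * ext, 0.75 * ext)
      for (t in ii) {
        df$x[t] <- pos[1]; df$y_m[t] <- pos[2]
        pt <- matrix(pos, 1, 2)
        df$x2[t] <- distance_to_features(pt, landscape, "primary_road")
        df$x3[t] <- distance_to_features(pt, landscape, "secondary_road")
        df$x4[t] <- distance_to_features(pt, landscape, "settlement")
        df$x1[t] <- min(df$x2[t], df$x3[t])
        mu_t <- linear_predictor(state, df[t, cols, drop = FALSE], spec)
        yr <- mu_t + stats::rnorm(1, 0, sqrt(state$sigma2))
        if (yr < 0) ntrunc <- ntrunc + 1L
        yv <- max(yr, 0)
        yobs[t] <- yv
        # random heading, rejecting directions that would leave the extent
        # so the realised step length always equals the movement rate
        step <- yv^2 * 1000
        for (try in 1:100) {
          ang <- stats::runif(1, 0, 2 * pi)
          cand <- pos + step * c(cos(ang), sin(ang))
          if (all(cand >= 0 & cand <= ext)) break
          cand <- pmin(pmax(cand, 0), ext)
        }
        pos <- cand
      }
    }
    trunc_rate <- ntrunc / n
    df$y <- yobs
    df$rate_kmh <- yobs^2
    keep <- acquired & c(acquired[-1L], FALSE) &
      c(df$animal[-1L] == df$animal[-n] &
          diff(as.numeric(df$timestamp)) == 3600, FALSE)
    records <- df[keep, ]
    fixes <- data.frame(animal_id = df$animal_id, sex = df$sex,
                        timestamp = df$timestamp, x = df$x, y = df$y_m,
                        stringsAsFactors = FALSE)[acquired, ]
    fixes <- apply_gps_error(fixes, truth$gps_error_mean_m)
    rownames(fixes) <- NULL
  }
  if (trunc_rate > 0.05) {
    warning(sprintf("%.1f%% of sqrt-rates truncated at zero; generating levels may be low",
                    100 * trunc_rate))
  }
  records <- records[, c("animal_id", "sex", "timestamp", "hour_index",
                         "season", "rate_kmh", "y", "x1", "x2", "x3", "x4")]
  rownames(records) <- NULL
  list(records = records, fixes = fixes, truth = truth,
       truncation_rate = trunc_rate)
}

#' Add isotropic GPS location error to fixes
#'
#' Adds independent Gaussian noise to x and y with the per-axis sd chosen
#' so the mean radial displacement equals `mean_error_m` (a radial
#' Rayleigh error has mean `sd * sqrt(pi/2)`, so `sd = mean / sqrt(pi/2)`).
#'
#' @param fixes fix data frame with `x`, `y` in meters.
#' @param mean_error_m target mean radial error (m, >= 0).
#' @param seed optional integer seed.
#' @return fix data frame with perturbed coordinates.
#' @export
apply_gps_error <- function(fixes, mean_error_m = 24.7, seed = NULL) {
  if (!is.numeric(mean_error_m) || mean_error_m < 0) stop("mean_error_m must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (mean_error_m == 0 || nrow(fixes) == 0L) return(fixes)
  sd_axis <- mean_error_m / sqrt(pi / 2)
  fixes$x <- fixes$x + stats::rnorm(nrow(fixes), 0, sd_axis)
  fixes$y <- fixes$y + stats::rnorm(nrow(fixes), 0, sd_axis)
  fixes
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: [simulate_truth()] then [simulate_records()].
#'
#' @param model model id or spec.
#' @param landscape optional `feature_set`.
#' @param seed integer seed for both stages.
#' @param ... passed to [simulate_truth()].
#' @return the [simulate_records()] result.
#' @export
simulate_study <- function(model = 9L, landscape = NULL, seed = 1L, ...) {
  truth <- simulate_truth(model = model, seed = seed, ...)
  simulate_records(truth, landscape = landscape, seed = seed)
}

#' Serialize a synthetic truth as JSON
#'
#' Writes every generating parameter and design field alongside a
#' generated dataset, so any synthetic study can be audited and re-run.
#'
#' @param truth a `synthetic_truth`.
#' @param path output JSON path.
#' @export
truth_to_json <- function(truth, path) {
  st <- truth$state
  obj <- list(spec_id = truth$spec$id, n_bears = truth$n_bears,
              sexes = truth$sexes, study_days = truth$study_days,
              acquisition_rate = truth$acquisition_rate,
              gps_error_mean_m = truth$gps_error_mean_m,
              start_year = truth$start_year, seed = truth$seed,
              lambda = apply(st$lambda, 2, identity, simplify = FALSE),
              omega = unname(st$omega), alpha = st$alpha, rho2 = st$rho2,
              fixed = as.list(st$fixed), beta = as.list(st$beta),
              phi = as.list(st$phi), nu = st$nu, psi = st$psi,
              sigma2 = st$sigma2)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
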