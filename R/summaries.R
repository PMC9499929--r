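# All result surfaces share one back-transform convention: the linear
# predictor is built on the sqrt(km/h) scale per posterior draw, floored at
# zero and squared to km/h, and only then summarised (never the square of a
# posterior mean). The credibility bands are the equal-tailed 2.5-97.5%
# quantiles of posterior_summary().

# Per-draw rate matrix (draws x 24 hours, km/h) for one (season, sex) cell,
# covariates held at `profile_km`.
cell_rate_draws <- function(fit, season, sex, profile_km, include_noise,
                            sqrt_scale = FALSE) {
  spec <- fit$spec
  lay <- fit$layout
  dr <- fit$draws
  strat <- lambda_stratum_of(spec, season, sex)
  lam_cols <- (strat - 1L) * 24L + 1:24
  eta <- dr[, lam_cols, drop = FALSE] + dr[, lay$alpha_col]
  fd <- fixed_design(spec, season, sex)
  for (col in seq_len(ncol(fd))) {
    if (fd[1L, col] > 0L) eta <- eta + dr[, lay$fixed_at + fd[1L, col]]
  }
  off <- 0L
  for (jpos in seq_along(spec$features)) {
    g <- if (spec$by_season) off + season else jpos
    b <- dr[, lay$beta_at + g]
    p <- dr[, lay$phi_at + g]
    eta <- eta + b * exp(-p * profile_km)
    off <- off + if (spec$by_season) 4L else 1L
  }
  if (sqrt_scale) return(eta)
  r <- pmax(eta, 0)^2
  if (include_noise) r <- r + dr[, lay$sigma2_col]
  r
}

new_activity_curve <- function(draws, stratum) {
  dimnames(draws) <- NULL
  structure(list(hours = 1:24,
                 mean_rate = colMeans(draws),
                 ci_low = unname(apply(draws, 2, stats::quantile, probs = 0.025)),
                 ci_high = unname(apply(draws, 2, stats::quantile, probs = 0.975)),
                 draws = draws, stratum = stratum),
            class = "activity_curve")
}

#' Posterior hourly activity curve
#'
#' The estimated movement rate (km/h) at each hour of the day with its 95%
#' credibility band. For each posterior draw the linear predictor is
#' evaluated on the sqrt scale for the requested stratum — hour effect,
#' population-level individual effect `alpha`, fixed sex/season terms, and
#' the anthropogenic terms at a far-distance covariate profile — floored at
#' zero and squared to km/h; mean and 2.5/97.5% quantiles are then taken
#' across draws. Leaving `season` or `sex` as `NULL` averages the
#' back-transformed rates across that dimension's levels per draw (so
#' `sex = NULL` is the 50:50 sex-ratio population curve).
#'
#' @param fit a [diel_fit()].
#' @param season season 1..4 (or code "sp","es","ls","fa"), or `NULL` to
#'   average over seasons.
#' @param sex 1/2 or "F"/"M", or `NULL` for the 50:50 population average.
#' @param profile_km distance (km) at which anthropogenic covariates are
#'   held; the default 4 km is effectively the asymptote given the decay
#'   prior (phi >= 0.75, practical range <= 4 km).
#' @param include_noise add the residual variance `sigma2` to each draw's
#'   squared predictor (a predictive-mean variant rather than the default
#'   typical-hour activity index).
#' @param average_scale average over pooled strata on the back-transformed
#'   `"rate"` (km/h) scale (default) or on the `"sqrt"` scale.
#' @return object of class `activity_curve` (hours, mean_rate, ci_low,
#'   ci_high, and the per-draw rate matrix).
#' @export
hourly_curve <- function(fit, season = NULL, sex = NULL, profile_km = 4,
                         include_noise = FALSE,
                         average_scale = c("rate", "sqrt")) {
  stopifnot(inherits(fit, "diel_fit"))
  average_scale <- match.arg(average_scale)
  season <- normalize_season(season)
  sex <- normalize_sex(sex)
  if (!is.null(sex) && fit$spec$hour == "hour_season" &&
      fit$spec$fixed %in% c("none", "season")) {
    stop("model ", fit$spec$id, " has no sex stratum")
  }
  seasons <- if (is.null(season)) 1:4 else season
  sexes <- if (is.null(sex)) 1:2 else sex
  grid <- expand.grid(season = seasons, sex = sexes)
  sqrt_scale <- average_scale == "sqrt"
  acc <- NULL
  for (g in seq_len(nrow(grid))) {
    cell <- cell_rate_draws(fit, grid$season[g], grid$sex[g], profile_km,
                            include_noise, sqrt_scale = sqrt_scale)
    acc <- if (is.null(acc)) cell else acc + cell
  }
  acc <- acc / nrow(grid)
  if (sqrt_scale) {
    acc <- pmax(acc, 0)^2
    if (include_noise) acc <- acc + fit$draws[, fit$layout$sigma2_col]
  }
  new_activity_curve(acc, list(season = season, sex = sex))
}

normalize_season <- function(season) {
  if (is.null(season)) return(NULL)
  if (is.character(season)) season <- match(season, SEASON_CODES)
  season <- as.integer(season)
  if (any(is.na(season) | season < 1L | season > 4L)) stop("invalid season")
  season
}

normalize_sex <- function(sex) {
  if (is.null(sex)) return(NULL)
  if (is.character(sex)) sex <- match(sex, SEX_CODES)
  sex <- as.integer(sex)
  if (any(is.na(sex) | sex < 1L | sex > 2L)) stop("invalid sex")
  sex
}

#' 50:50 sex-ratio population curve from two sex curves
#'
#' Averages the two sexes' back-transformed hourly rates draw by draw and
#' re-summarises, i.e. the curve of a population with equal numbers of
#' females and males.
#'
#' @param curve_F,curve_M `activity_curve` objects for the two sexes over
#'   the same hours and draws.
#' @return an `activity_curve`.
#' @export
population_curve_5050 <- function(curve_F, curve_M) {
  stopifnot(inherits(curve_F, "activity_curve"),
            inherits(curve_M, "activity_curve"))
  if (!identical(curve_F$hours, curve_M$hours) ||
      !all(dim(curve_F$draws) == dim(curve_M$draws))) {
    stop("curves have mismatched hours or draws")
  }
  new_activity_curve((curve_F$draws + curve_M$draws) / 2,
                     list(season = curve_F$stratum$season, sex = NULL))
}

#' Classify hours as active or inactive
#'
#' An hour is active when its posterior mean rate exceeds the 24-hour
#' average of the curve's mean rates (the across-hours mean as activity
#' threshold); ties count as inactive.
#'
#' @param curve an `activity_curve`.
#' @return list with integer vectors `active` and `inactive` and the
#'   `threshold` (km/h).
#' @export
classify_active_hours <- function(curve) {
  stopifnot(inherits(curve, "activity_curve"))
  if (any(!is.finite(curve$mean_rate))) stop("curve has non-finite means")
  thr <- mean(curve$mean_rate)
  act <- which(curve$mean_rate > thr)
  list(active = as.integer(act),
       inactive = as.integer(setdiff(1:24, act)),
       threshold = thr)
}

#' Movement-rate table by sex, season and period of day
#'
#' Posterior mean and SD of the back-transformed movement rate averaged
#' over each hour set (full 24 h, active hours, inactive hours), for each
#' sex (and both pooled 50:50) and each season (and all pooled).
#'
#' @param fit a [diel_fit()].
#' @param partition hour partition from [classify_active_hours()]; by
#'   default computed from the pooled population curve.
#' @param profile_km covariate profile passed to [hourly_curve()].
#' @return data frame `sex, season, period, mean, sd` (km/h).
#' @export
movement_rate_table <- function(fit, partition = NULL, profile_km = 4) {
  if (is.null(partition)) {
    partition <- classify_active_hours(hourly_curve(fit, profile_km = profile_km))
  }
  sets <- list(`24-h` = 1:24, active = partition$active,
               inactive = partition$inactive)
  sex_opts <- list(both = NULL, F = 1L, M = 2L)
  season_opts <- c(list(all = NULL), stats::setNames(as.list(1:4), SEASON_CODES))
  rows <- list()
  for (sx in names(sex_opts)) {
    for (se in names(season_opts)) {
      cur <- hourly_curve(fit, season = season_opts[[se]],
                          sex = sex_opts[[sx]], profile_km = profile_km)
      for (p in names(sets)) {
        hrs <- sets[[p]]
        if (!length(hrs)) next
        per_draw <- rowMeans(cur$draws[, hrs, drop = FALSE])
        rows[[length(rows) + 1L]] <-
          data.frame(sex = sx, season = se, period = p,
                     mean = mean(per_draw), sd = stats::sd(per_draw),
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Movement-rate response to distance from a feature class
#'
#' The estimated movement rate (km/h) along a grid of distances to one
#' anthropogenic feature class in one season, other terms held at a stated
#' profile: per draw the baseline is the hour-averaged sqrt-scale predictor
#' (with the other features at `profile_km`), the feature's exponential
#' term `beta exp(-phi x)` is added along the grid, and the result is
#' floored at zero, squared, and summarised. Also reports whether the 95%
#' credibility interval of the relevant `beta` excludes zero.
#'
#' @param fit a [diel_fit()].
#' @param season season 1..4 or code.
#' @param feature feature number (1 = all roads, 2 = primary roads,
#'   3 = secondary roads, 4 = settlements) — must be in the model's block.
#' @param distance_grid_km distances (km) to evaluate.
#' @param sex 1/2, "F"/"M" or `NULL` (50:50 average).
#' @param profile_km profile distance for the other features.
#' @return data frame `distance_km, mean, ci_low, ci_high` with attributes
#'   `beta_ci` (the interval) and `ci_excludes_zero`.
#' @export
anthropogenic_response <- function(fit, season, feature,
                                   distance_grid_km = seq(0, 4, by = 0.1),
                                   sex = NULL, profile_km = 4) {
  stopifnot(inherits(fit, "diel_fit"))
  spec <- fit$spec
  season <- normalize_season(season)
  sex <- normalize_sex(sex)
  stopifnot(length(season) == 1L)
  jpos <- match(feature, spec$features)
  if (is.na(jpos)) {
    stop("model ", spec$id, " has no anthropogenic term for feature x", feature)
  }
  lay <- fit$layout
  dr <- fit$draws
  g <- if (spec$by_season) (jpos - 1L) * 4L + season else jpos
  b <- dr[, lay$beta_at + g]
  p <- dr[, lay$phi_at + g]

  sexes <- if (is.null(sex)) 1:2 else sex
  # hour-averaged sqrt-scale baseline per draw, feature of interest excluded
  base_of <- function(s) {
    eta <- rowMeans(cell_rate_draws(fit, season, s, profile_km,
                                    include_noise = FALSE, sqrt_scale = TRUE))
    eta - b * exp(-p * profile_km)
  }
  out <- matrix(0, nrow(dr), length(distance_grid_km))
  for (s in sexes) {
    eta0 <- base_of(s)
    for (i in seq_along(distance_grid_km)) {
      out[, i] <- out[, i] +
        pmax(eta0 + b * exp(-p * distance_grid_km[i]), 0)^2
    }
  }
  out <- out / length(sexes)
  beta_ci <- stats::quantile(b, c(0.025, 0.975))
  res <- data.frame(distance_km = distance_grid_km,
                    mean = colMeans(out),
                    ci_low = apply(out, 2, stats::quantile, probs = 0.025),
                    ci_high = apply(out, 2, stats::quantile, probs = 0.975))
  attr(res, "beta_ci") <- unname(beta_ci)
  attr(res, "ci_excludes_zero") <- unname(beta_ci[1] > 0 || beta_ci[2] < 0)
  res
}

#' @export
print.activity_curve <- function(x, ...) {
  st <- x$stratum
  cat(sprintf("activity curve (%s, %s): mean rate %.3f km/h, peak %.3f at hour %d\n",
              if (is.null(st$season)) "all seasons" else paste(SEASON_CODES[st$season], collapse = "/"),
              if (is.null(st$sex)) "50:50 sexes" else SEX_CODES[st$sex],
              mean(x$mean_rate), max(x$mean_rate), which.max(x$mean_rate)))
  invisible(x)
}

#' @export
plot.activity_curve <- function(x, add_sun_lines = NULL, ...) {
  args <- list(...)
  if (is.null(args$ylim)) args$ylim <- c(0, max(x$ci_high) * 1.05)
  do.call(graphics::plot,
          c(list(x = x$hours, y = x$mean_rate, type = "n",
                 xlab = "hour of day", ylab = "movement rate (km/h)"), args))
  graphics::polygon(c(x$hours, rev(x$hours)), c(x$ci_low, rev(x$ci_high)),
                    col = "grey85", border = NA)
  graphics::lines(x$hours, x$mean_rate, lwd = 2)
  if (!is.null(add_sun_lines)) {
    graphics::abline(v = add_sun_lines, col = "grey40", lty = 1)
  }
  invisible(x)
}

#' @export
plot.diel_fit <- function(x, season = NULL, sex = NULL, ...) {
  plot(hourly_curve(x, season = season, sex = sex), ...)
}
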