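#' Read a GPS fix table
#'
#' Reads fixes from CSV with header `animal_id,sex,timestamp,x,y`:
#' ISO-8601 timestamps, planar projected coordinates in meters. Timestamps
#' are interpreted in a single fixed offset (UTC), so hourly spacing is
#' never distorted by DST transitions.
#'
#' @param path CSV file path.
#' @return data frame of fixes, sorted by animal and time.
#' @export
read_gps_fixes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  # a single-sex column of "F"s would otherwise parse as logical
  if (is.logical(df$sex)) df$sex <- ifelse(df$sex, "T", "F")
  need <- c("animal_id", "sex", "timestamp", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fix table lacks column(s): ", paste(miss, collapse = ", "))
  df$timestamp <- parse_timestamp(df$timestamp)
  if (any(is.na(df$timestamp))) stop("unparseable timestamp in fix table")
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (any(!is.finite(df$x)) || any(!is.finite(df$y))) stop("non-finite coordinates")
  df <- df[order(df$animal_id, df$timestamp), need]
  rownames(df) <- NULL
  df
}

parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(x, tz = "UTC"))
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  alt <- is.na(out)
  if (any(alt)) {
    out[alt] <- as.POSIXct(x[alt], tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  }
  alt <- is.na(out)
  if (any(alt)) out[alt] <- as.POSIXct(x[alt], tz = "UTC", format = "%Y-%m-%d")
  out
}

#' Standardize fixes to one location per hour
#'
#' Within each animal and clock hour keeps the single fix whose timestamp is
#' closest to the top of that hour (smallest offset past the hour; ties go
#' to the earlier fix). Deterministic; already-hourly series pass through
#' unchanged.
#'
#' @param fixes fix data frame ([read_gps_fixes()] schema).
#' @return fix data frame with at most one row per animal per hour.
#' @export
standardize_hourly <- function(fixes) {
  if (nrow(fixes) == 0L) return(fixes)
  ord <- order(fixes$animal_id, fixes$timestamp)
  fixes <- fixes[ord, ]
  tt <- as.numeric(fixes$timestamp)
  bucket <- floor(tt / 3600)
  offset <- tt - bucket * 3600
  key <- paste(fixes$animal_id, bucket)
  # stable order => which.min keeps the earlier fix on ties
  keep <- unsplit(lapply(split(seq_along(key), key), function(ii) {
    sel <- logical(length(ii)); sel[which.min(offset[ii])] <- TRUE; sel
  }), key)
  out <- fixes[keep, ]
  rownames(out) <- NULL
  out
}

#' Screen fixes with a symmetric speed filter
#'
#' Flags a fix as an outlier when the straight-line speed to **both** its
#' temporal neighbours within the animal's series exceeds `max_speed_kmh`:
#' a genuine relocation error makes both adjacent steps implausibly fast,
#' while a fast-but-real step only affects one. End fixes (one neighbour)
#' are never removed.
#'
#' @param fixes hourly-standardized fix data frame.
#' @param max_speed_kmh speed threshold in km/h (> 0); default 10 is
#'   generous for a brown bear.
#' @return list with `fixes` (retained) and `removed` (flagged rows).
#' @export
screen_outliers <- function(fixes, max_speed_kmh = 10) {
  if (!is.numeric(max_speed_kmh) || length(max_speed_kmh) != 1L ||
      !is.finite(max_speed_kmh) || max_speed_kmh <= 0) {
    stop("max_speed_kmh must be a positive number")
  }
  if (nrow(fixes) == 0L) return(list(fixes = fixes, removed = fixes))
  drop <- logical(nrow(fixes))
  for (ii in split(seq_len(nrow(fixes)), fixes$animal_id)) {
    n <- length(ii)
    if (n < 3L) next
    x <- fixes$x[ii]; y <- fixes$y[ii]
    dt_h <- diff(as.numeric(fixes$timestamp[ii])) / 3600
    sp <- sqrt(diff(x)^2 + diff(y)^2) / 1000 / dt_h   # km/h per step
    bad <- sp[-length(sp)] > max_speed_kmh & sp[-1L] > max_speed_kmh
    drop[ii[c(FALSE, bad, FALSE)]] <- TRUE
  }
  list(fixes = {o <- fixes[!drop, ]; rownames(o) <- NULL; o},
       removed = {o <- fixes[drop, ]; rownames(o) <- NULL; o})
}

#' Hourly movement rates from standardized fixes
#'
#' Emits one record per pair of fixes exactly one hour apart within an
#' animal: the planar Euclidean distance between them in km (the hourly
#' movement rate, km/h) and its square root `y`, the model's response.
#' Pairs separated by more than one hour (missed fixes) yield no record.
#' Each record carries the attributes of the **starting** fix of the step.
#'
#' @param fixes screened hourly fix data frame.
#' @return data frame `animal_id, sex, timestamp, rate_kmh, y`.
#' @export
movement_rates <- function(fixes) {
  pieces <- lapply(split(seq_len(nrow(fixes)), fixes$animal_id), function(ii) {
    if (length(ii) < 2L) return(NULL)
    dt <- diff(as.numeric(fixes$timestamp[ii]))
    ok <- abs(dt - 3600) < 1e-6
    if (!any(ok)) return(NULL)
    a <- ii[-length(ii)][ok]; b <- ii[-1L][ok]
    rate <- sqrt((fixes$x[b] - fixes$x[a])^2 + (fixes$y[b] - fixes$y[a])^2) / 1000
    data.frame(animal_id = fixes$animal_id[a], sex = fixes$sex[a],
               timestamp = fixes$timestamp[a], rate_kmh = rate,
               y = sqrt(rate), stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) {
    return(data.frame(animal_id = character(0), sex = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      rate_kmh = numeric(0), y = numeric(0)))
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Hour-of-day index
#'
#' Maps a timestamp to the model's hour index: clock hours 1..23 map to
#' themselves and midnight (00:xx) maps to 24, so index 24 and index 1 are
#' one hour apart on the circular clock.
#'
#' @param timestamp POSIXct (fixed offset) or parseable string.
#' @return integer vector in 1..24.
#' @export
hour_index <- function(timestamp) {
  ts <- parse_timestamp(timestamp)
  h <- as.integer(format(ts, "%H", tz = "UTC"))
  ifelse(h == 0L, 24L, h)
}

#' Dietary season of a date
#'
#' The four dietary seasons of the study population: spring (March-May),
#' early summer (June-July), late summer (August-September) and fall
#' (October to mid-December, cut at December 15 inclusive). Dates outside
#' the March 1 - December 15 active period return `NA` (records excluded).
#'
#' @param date Date/POSIXct or parseable string.
#' @return integer vector in 1..4 (`NA` outside the active period).
#' @export
season_of <- function(date) {
  ts <- parse_timestamp(date)
  m <- as.integer(format(ts, "%m", tz = "UTC"))
  d <- as.integer(format(ts, "%d", tz = "UTC"))
  s <- rep(NA_integer_, length(m))
  s[m %in% 3:5] <- 1L
  s[m %in% 6:7] <- 2L
  s[m %in% 8:9] <- 3L
  s[m %in% 10:11 | (m == 12L & d <= 15L)] <- 4L
  s
}

season_code <- function(season) SEASON_CODES[season]

#' Minimum planar distance from points to a feature class
#'
#' Minimum distance (km) from each point to the nearest feature of the
#' requested class: point-to-segment distance for road polylines,
#' point-to-point for settlement centroids. Planar geometry in meters.
#'
#' @param points two-column matrix (or data frame) of x, y in meters.
#' @param features a feature set from [read_features_geojson()] or
#'   [simulate_landscape()].
#' @param type one of `"primary_road"`, `"secondary_road"`, `"settlement"`,
#'   or `"road"` (both road classes pooled).
#' @return numeric vector of distances in km.
#' @export
distance_to_features <- function(points, features, type) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("points must have two columns (x, y)")
  types <- if (type == "road") c("primary_road", "secondary_road") else type
  feats <- Filter(function(f) f$ftype %in% types, features)
  if (!length(feats)) stop("no feature of class '", type, "' in the feature set")
  segs <- do.call(rbind, lapply(feats, function(f) {
    cc <- f$coords
    if (nrow(cc) == 1L) cbind(cc[1, 1], cc[1, 2], cc[1, 1], cc[1, 2])
    else cbind(cc[-nrow(cc), 1], cc[-nrow(cc), 2], cc[-1, 1], cc[-1, 2])
  }))
  out <- numeric(nrow(pts))
  chunk <- 2000L
  for (s in seq(1L, nrow(pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pts))
    out[s:e] <- point_segments_min_dist(pts[s:e, , drop = FALSE], segs)
  }
  out / 1000
}

# Minimum over segments of the point-to-segment distance (meters).
point_segments_min_dist <- function(pts, segs) {
  px <- pts[, 1]; py <- pts[, 2]
  ax <- segs[, 1]; ay <- segs[, 2]; bx <- segs[, 3]; by <- segs[, 4]
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  dx <- outer(px, ax, "-"); dy <- outer(py, ay, "-")
  tt <- sweep(dx * rep(vx, each = length(px)) + dy * rep(vy, each = length(px)),
              2, pmax(len2, .Machine$double.eps), "/")
  tt <- pmin(pmax(tt, 0), 1)
  cx <- sweep(tt, 2, vx, "*") - dx
  cy <- sweep(tt, 2, vy, "*") - dy
  d2 <- cx^2 + cy^2
  sqrt(apply(d2, 1, min))
}

#' Read / write a typed feature set as GeoJSON
#'
#' Features are a GeoJSON FeatureCollection in which every feature carries a
#' property `ftype` in `{primary_road, secondary_road, settlement}`; roads
#' are LineStrings and settlements Points, with planar coordinates in
#' meters.
#'
#' @param path GeoJSON file path.
#' @return `read_features_geojson` returns a list of features (each with
#'   `ftype` and a coordinate matrix `coords`); `write_features_geojson`
#'   returns `path` invisibly.
#' @export
read_features_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  feats <- lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    ft <- f$properties$ftype
    if (is.null(ft) || !ft %in% c("primary_road", "secondary_road", "settlement")) {
      stop("feature ", i, ": missing or invalid property 'ftype'")
    }
    geom <- f$geometry
    coords <- if (identical(geom$type, "Point")) {
      matrix(as.numeric(unlist(geom$coordinates)), 1, 2)
    } else if (identical(geom$type, "LineString")) {
      do.call(rbind, lapply(geom$coordinates, function(p) as.numeric(unlist(p))))
    } else stop("feature ", i, ": unsupported geometry type ", geom$type)
    list(ftype = ft, coords = coords)
  })
  structure(feats, class = "feature_set")
}

#' @rdname read_features_geojson
#' @param features list of features to write.
#' @export
write_features_geojson <- function(features, path) {
  fl <- lapply(features, function(f) {
    if (f$ftype == "settlement") {
      geom <- list(type = "Point", coordinates = as.numeric(f$coords[1, ]))
    } else {
      geom <- list(type = "LineString",
                   coordinates = lapply(seq_len(nrow(f$coords)),
                                        function(i) as.numeric(f$coords[i, ])))
    }
    list(type = "Feature", properties = list(ftype = f$ftype), geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = fl), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build the model's observation table from raw fixes
#'
#' Full preprocessing pipeline: hourly standardization, symmetric-speed
#' outlier screening, hourly movement rates, hour/season labels, and the
#' distance covariates `x1`..`x4` (km). Each movement record inherits the
#' hour index, season and covariates of the starting fix of its step;
#' records outside the March-mid-December active period are dropped.
#'
#' @param fixes fix data frame ([read_gps_fixes()] schema).
#' @param features optional feature set for computing distances.
#' @param covariates optional precomputed covariates, a data frame
#'   `animal_id, timestamp, x2_km, x3_km, x4_km` (`x1` derived as
#'   `min(x2, x3)`), used when no feature set is given.
#' @param max_speed_kmh outlier-screening threshold (km/h).
#' @return observation data frame `animal_id, sex, timestamp, hour_index,
#'   season, rate_kmh, y, x1, x2, x3, x4`.
#' @export
build_observations <- function(fixes, features = NULL, covariates = NULL,
                               max_speed_kmh = 10) {
  hourly <- standardize_hourly(fixes)
  screened <- screen_outliers(hourly, max_speed_kmh)$fixes
  rec <- movement_rates(screened)
  rec$hour_index <- hour_index(rec$timestamp)
  rec$season <- season_of(rec$timestamp)
  if (!is.null(features)) {
    key <- paste(screened$animal_id, as.numeric(screened$timestamp))
    m <- match(paste(rec$animal_id, as.numeric(rec$timestamp)), key)
    pts <- cbind(screened$x[m], screened$y[m])
    rec$x2 <- distance_to_features(pts, features, "primary_road")
    rec$x3 <- distance_to_features(pts, features, "secondary_road")
    rec$x4 <- distance_to_features(pts, features, "settlement")
    rec$x1 <- pmin(rec$x2, rec$x3)
  } else if (!is.null(covariates)) {
    covariates$timestamp <- parse_timestamp(covariates$timestamp)
    m <- match(paste(rec$animal_id, as.numeric(rec$timestamp)),
               paste(covariates$animal_id, as.numeric(covariates$timestamp)))
    if (any(is.na(m))) stop("covariate table lacks rows for some records")
    rec$x2 <- covariates$x2_km[m]
    rec$x3 <- covariates$x3_km[m]
    rec$x4 <- covariates$x4_km[m]
    rec$x1 <- pmin(rec$x2, rec$x3)
  } else {
    rec$x1 <- rec$x2 <- rec$x3 <- rec$x4 <- NA_real_
  }
  rec <- rec[!is.na(rec$season), c("animal_id", "sex", "timestamp",
                                   "hour_index", "season", "rate_kmh", "y",
                                   "x1", "x2", "x3", "x4")]
  rownames(rec) <- NULL
  rec
}

#' Write / read an observation table
#'
#' CSV with the [build_observations()] schema.
#'
#' @param obs observation data frame.
#' @param path CSV file path.
#' @export
write_observations <- function(obs, path) {
  out <- obs
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.logical(df$sex)) df$sex <- ifelse(df$sex, "T", "F")
  need <- c("animal_id", "sex", "timestamp", "hour_index", "season",
            "rate_kmh", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("observation table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$timestamp <- parse_timestamp(df$timestamp)
  df
}
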