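test_that("hourly standardization keeps the fix closest to the top of each hour", {
  fx <- make_fixes(n = 3)
  extra <- fx[2, ]
  extra$timestamp <- extra$timestamp + 30 * 60     # same hour, minute 30
  out <- standardize_hourly(rbind(fx, extra))
  expect_identical(nrow(out), 3L)
  expect_identical(out$timestamp, fx$timestamp)    # minute-00 fixes retained

  # already-hourly series passes unchanged
  expect_identical(standardize_hourly(fx), fx)

  # empty input
  expect_identical(nrow(standardize_hourly(fx[0, ])), 0L)
})

test_that("hourly standardization reduces a 29,796-row table to 26,880", {
  # 18 animals with hourly base schedules totalling 26,880 rows, plus
  # exactly 2,916 duplicate-hour surplus rows at minute 30.
  per_animal <- rep(26880 %/% 18, 18) + rep(c(1L, 0L), c(6, 12))
  stopifnot(sum(per_animal) == 26880)
  fixes <- do.call(rbind, lapply(seq_len(18), function(k) {
    make_fixes(animal_id = sprintf("b%02d", k),
               sex = if (k <= 11) "F" else "M", n = per_animal[k])
  }))
  set.seed(42)
  dup <- fixes[sample.int(nrow(fixes), 2916), ]
  dup$timestamp <- dup$timestamp + 30 * 60
  full <- rbind(fixes, dup)
  expect_identical(nrow(full), 29796L)
  out <- standardize_hourly(full)
  expect_identical(nrow(out), 26880L)
})

test_that("symmetric speed filter removes teleported fixes only", {
  fx <- make_fixes(n = 5, step_m = 100)       # ~0.1 km/h, well under threshold
  fx$x[3] <- fx$x[3] + 50000                  # 50 km jump to both neighbours
  res <- screen_outliers(fx, max_speed_kmh = 10)
  expect_identical(nrow(res$fixes), 4L)
  expect_identical(res$removed$timestamp, fx$timestamp[3])

  # all speeds below threshold: identity
  ok <- make_fixes(n = 6, step_m = 100)
  expect_identical(screen_outliers(ok, 10)$fixes, ok)

  # two-fix series: no fix has two neighbours
  two <- make_fixes(n = 2, step_m = 90000)
  expect_identical(screen_outliers(two, 10)$fixes, two)

  expect_error(screen_outliers(fx, 0), "positive")
  expect_error(screen_outliers(fx, -3), "positive")
})

test_that("movement rates are per-km hourly Euclidean steps on the sqrt scale", {
  fx <- make_fixes(n = 3, step_m = 300)
  rec <- movement_rates(fx)
  expect_equal(rec$rate_kmh, c(0.3, 0.3))
  expect_equal(rec$y, sqrt(c(0.3, 0.3)), tolerance = 1e-12)
  expect_equal(rec$y[1], 0.547723, tolerance = 1e-6)
  expect_identical(rec$timestamp, fx$timestamp[1:2])  # starting-fix attribution

  # identical consecutive positions
  still <- make_fixes(n = 2, step_m = 0)
  expect_equal(movement_rates(still)$rate_kmh, 0)

  # a 2-h gap yields no record across the gap (only the 3->4 pair remains)
  gap <- make_fixes(n = 4)
  gap <- gap[-2, ]
  expect_identical(nrow(movement_rates(gap)), 1L)
})

test_that("record count equals the brute-force consecutive-hour pair count", {
  set.seed(7)
  for (rep in 1:5) {
    fixes <- do.call(rbind, lapply(1:3, function(k) {
      n <- sample(5:40, 1)
      fx <- make_fixes(animal_id = paste0("a", k), n = n)
      fx[sort(sample.int(n, sample(3:n, 1))), ]       # random missingness
    }))
    got <- nrow(movement_rates(fixes))
    want <- sum(vapply(split(fixes, fixes$animal_id), function(d) {
      tt <- as.numeric(d$timestamp)
      cnt <- 0L
      for (i in seq_along(tt)[-1]) if (tt[i] - tt[i - 1] == 3600) cnt <- cnt + 1L
      cnt
    }, integer(1)))
    expect_identical(got, want)
  }
})

test_that("hour index maps midnight to 24 and is invariant to 24-h shifts", {
  expect_identical(hour_index(as.POSIXct("2008-04-01 00:00:00", tz = "UTC")), 24L)
  expect_identical(hour_index(as.POSIXct("2008-04-01 13:00:00", tz = "UTC")), 13L)
  expect_identical(hour_index(as.POSIXct("2008-04-01 23:59:00", tz = "UTC")), 23L)
  ts <- as.POSIXct("2008-04-01 00:00:00", tz = "UTC") + 3600 * 0:47
  expect_identical(hour_index(ts), hour_index(ts + 86400))
})

test_that("dietary seasons follow the four calendar windows", {
  expect_identical(season_of("2008-04-15"), 1L)   # spring: March-May
  expect_identical(season_of("2008-06-01"), 2L)   # early summer: June-July
  expect_identical(season_of("2008-08-31"), 3L)   # late summer: Aug-Sep
  expect_identical(season_of("2008-12-15"), 4L)   # fall ends mid-December
  expect_identical(season_of("2008-12-20"), NA_integer_)
  expect_identical(season_of("2008-02-28"), NA_integer_)
  expect_identical(season_of(c("2008-03-01", "2008-10-01")), c(1L, 4L))
})

test_that("feature distances match the exhaustive segment oracle", {
  set.seed(11)
  feats <- lapply(1:100, function(i) {
    list(ftype = "secondary_road", coords = matrix(runif(4, 0, 30000), 2, 2))
  })
  class(feats) <- "feature_set"
  pts <- matrix(runif(40, 0, 30000), 20, 2)
  got <- distance_to_features(pts, feats, "secondary_road")
  want <- apply(pts, 1, function(p) {
    min(vapply(feats, function(f)
      oracle_segment_dist(p, f$coords[1, ], f$coords[2, ]), numeric(1)))
  }) / 1000
  expect_equal(got, want, tolerance = 1e-5)

  # translation and rotation invariance
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift <- c(1234, -987)
  feats2 <- lapply(feats, function(f) {
    f$coords <- sweep(f$coords %*% t(R), 2, -shift)
    f
  })
  class(feats2) <- "feature_set"
  got2 <- distance_to_features(sweep(pts %*% t(R), 2, -shift), feats2,
                               "secondary_road")
  expect_equal(got2, got, tolerance = 1e-8)
})

test_that("feature distance handles points, zero distance, and missing classes", {
  feats <- structure(list(
    list(ftype = "primary_road", coords = rbind(c(0, 0), c(1000, 0))),
    list(ftype = "settlement", coords = matrix(c(2000, 1000), 1, 2))
  ), class = "feature_set")
  expect_equal(distance_to_features(rbind(c(500, 0)), feats, "primary_road"), 0)
  expect_equal(distance_to_features(rbind(c(2000, 0)), feats, "settlement"), 1)
  expect_error(distance_to_features(rbind(c(0, 0)), feats, "secondary_road"),
               "secondary_road")
})

test_that("observation tables carry the full pipeline schema and x1 = min(x2, x3)", {
  feats <- structure(list(
    list(ftype = "primary_road", coords = rbind(c(0, 0), c(0, 50000))),
    list(ftype = "secondary_road", coords = rbind(c(8000, 0), c(8000, 50000))),
    list(ftype = "settlement", coords = matrix(c(4000, 25000), 1, 2))
  ), class = "feature_set")
  fx <- make_fixes(n = 30, x = seq(1000, 7000, length.out = 30),
                   y = seq(20000, 30000, length.out = 30))
  obs <- build_observations(fx, features = feats)
  expect_identical(names(obs), c("animal_id", "sex", "timestamp", "hour_index",
                                 "season", "rate_kmh", "y", "x1", "x2", "x3", "x4"))
  expect_equal(obs$x1, pmin(obs$x2, obs$x3))
  expect_equal(obs$y, sqrt(obs$rate_kmh), tolerance = 1e-12)
  expect_true(all(obs$hour_index %in% 1:24))
  expect_true(all(obs$season %in% 1:4))

  # covariate-table path and CSV round trip
  cov <- data.frame(animal_id = fx$animal_id, timestamp = fx$timestamp,
                    x2_km = 1.5, x3_km = 0.5, x4_km = 2)
  obs2 <- build_observations(fx, covariates = cov)
  expect_equal(unique(obs2$x1), 0.5)
  tmp <- tempfile(fileext = ".csv")
  write_observations(obs2, tmp)
  back <- read_observations(tmp)
  expect_equal(back$y, obs2$y, tolerance = 1e-9)
  expect_identical(back$hour_index, obs2$hour_index)
})
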