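test_that("degenerate draws back-transform by squaring the sqrt-scale predictor", {
  # single draw with predictor 0.5 at every hour: rate 0.25, zero-width CI
  dr <- zero_draws(9, 1)
  dr[, "alpha"] <- 0.5
  fit <- make_stub_fit(9, dr)
  cur <- hourly_curve(fit)
  expect_equal(cur$mean_rate, rep(0.25, 24))
  expect_equal(cur$ci_low, cur$ci_high)
  expect_equal(unname(cur$ci_low), rep(0.25, 24))

  # all-zero draws give a flat zero curve
  fit0 <- make_stub_fit(9, zero_draws(9, 3))
  expect_equal(hourly_curve(fit0)$mean_rate, rep(0, 24))
})

test_that("curves summarise per-draw squared predictors, never squared means", {
  set.seed(14)
  dr <- zero_draws(1, 500)
  dr[, "alpha"] <- rnorm(500, 0.5, 0.2)
  fit <- make_stub_fit(1, dr)
  cur <- hourly_curve(fit)
  per_draw <- pmax(dr[, "alpha"], 0)^2
  expect_equal(unname(cur$mean_rate[7]), mean(per_draw), tolerance = 1e-12)
  # squaring the posterior mean would understate the curve
  expect_gt(cur$mean_rate[7], mean(dr[, "alpha"])^2)
  expect_equal(unname(cur$ci_low[1]), oracle_quantile(per_draw, 0.025),
               tolerance = 1e-12)
})

test_that("the 50:50 population curve averages sexes on the rate scale", {
  mk <- function(rate) bearcadian:::new_activity_curve(
    matrix(rate, 40, 24), list(season = NULL, sex = NULL))
  expect_equal(population_curve_5050(mk(0.1), mk(0.1))$mean_rate, rep(0.1, 24))
  expect_equal(population_curve_5050(mk(0.1), mk(0.3))$mean_rate, rep(0.2, 24))

  set.seed(3)
  a <- matrix(rexp(40 * 24, 5), 40, 24)
  b <- matrix(rexp(40 * 24, 3), 40, 24)
  pop <- population_curve_5050(
    bearcadian:::new_activity_curve(a, list(season = NULL, sex = 1L)),
    bearcadian:::new_activity_curve(b, list(season = NULL, sex = 2L)))
  expect_equal(pop$mean_rate, colMeans((a + b) / 2), tolerance = 1e-12)
  expect_error(population_curve_5050(mk(0.1),
    bearcadian:::new_activity_curve(matrix(0.1, 39, 24), list())), "mismatch")

  # hourly_curve with sex = NULL equals the explicit 50:50 combination
  dr <- zero_draws(9, 30)
  dr[, "alpha"] <- runif(30, 0.3, 0.7)
  dr[, "mu_M" == colnames(dr)] <- 0   # model 9 has xi, not mu; keep zeros
  fit <- make_stub_fit(9, dr)
  cf <- hourly_curve(fit, sex = "F"); cm <- hourly_curve(fit, sex = "M")
  expect_equal(hourly_curve(fit)$mean_rate,
               population_curve_5050(cf, cm)$mean_rate, tolerance = 1e-12)
})

test_that("hours are classified active by the across-hours mean threshold", {
  mkcurve <- function(means) bearcadian:::new_activity_curve(
    matrix(rep(means, each = 2), 2, 24), list(season = NULL, sex = NULL))
  # constant curve: ties are inactive
  expect_length(classify_active_hours(mkcurve(rep(0.2, 24)))$active, 0)

  # one spike above a flat baseline
  spike <- rep(0.2, 24); spike[11] <- 0.5
  part <- classify_active_hours(mkcurve(spike))
  expect_identical(part$active, 11L)
  expect_identical(part$inactive, setdiff(1:24, 11L))
  expect_equal(part$threshold, mean(spike))

  # bimodal crepuscular curve contains both peaks
  lam <- crepuscular_lambda(peak_hours = c(5, 19))
  part2 <- classify_active_hours(mkcurve(pmax(0.55 + lam, 0)^2))
  expect_true(all(c(5L, 19L) %in% part2$active))
})

test_that("movement-rate tables average draws over hour sets per stratum", {
  dr <- zero_draws(9, 4)
  dr[, "alpha"] <- sqrt(0.2)           # flat 0.2 km/h everywhere
  fit <- make_stub_fit(9, dr)
  tab <- movement_rate_table(fit)
  expect_true(all(abs(tab$mean - 0.2) < 1e-12))
  expect_true(all(tab$sd == 0))
  expect_identical(sort(unique(tab$period)), sort(c("24-h", "inactive")))

  # random fit: active-period mean exceeds inactive by construction
  set.seed(6)
  dr2 <- zero_draws(9, 60)
  lam <- crepuscular_lambda()
  for (h in 1:24) {
    cols <- grep(sprintf("^lambda_.*_h%02d$", h), colnames(dr2))
    dr2[, cols] <- lam[h] + rnorm(60, 0, 0.03)
  }
  dr2[, "alpha"] <- 0.55
  fit2 <- make_stub_fit(9, dr2)
  part <- classify_active_hours(hourly_curve(fit2))
  tab2 <- movement_rate_table(fit2, partition = part)
  wide <- split(tab2$mean, tab2$period)
  expect_true(all(wide$active > wide$inactive))

  # matches a brute-force draw-averaging oracle for one cell
  cur_f_sp <- hourly_curve(fit2, season = 1, sex = 1)
  cell <- tab2[tab2$sex == "F" & tab2$season == "sp" & tab2$period == "24-h", ]
  expect_equal(cell$mean, mean(rowMeans(cur_f_sp$draws)), tolerance = 1e-12)
  expect_equal(cell$sd, sd(rowMeans(cur_f_sp$draws)), tolerance = 1e-12)
})

test_that("distance-response curves decay and flag betas whose CI excludes zero", {
  dr <- zero_draws(9, 200)
  dr[, "alpha"] <- 0.5
  set.seed(44)
  dr[, "beta_x2_sp"] <- rnorm(200, 0.4, 0.05)
  fit <- make_stub_fit(9, dr)

  resp <- anthropogenic_response(fit, season = "sp", feature = 2)
  expect_true(all(diff(resp$mean) < 0))          # beta > 0: decaying rate
  expect_true(attr(resp, "ci_excludes_zero"))
  expect_equal(attr(resp, "beta_ci"),
               unname(quantile(dr[, "beta_x2_sp"], c(0.025, 0.975))),
               tolerance = 1e-12)

  # beta centred at zero: flat curve, flag off
  dr0 <- zero_draws(9, 200)
  dr0[, "alpha"] <- 0.5
  dr0[, "beta_x2_sp"] <- rnorm(200, 0, 0.05)
  fit0 <- make_stub_fit(9, dr0)
  resp0 <- anthropogenic_response(fit0, season = "sp", feature = 2)
  expect_false(attr(resp0, "ci_excludes_zero"))
  expect_lt(max(resp0$mean) - min(resp0$mean), 0.02)

  expect_error(anthropogenic_response(fit, season = "sp", feature = 1), "x1")
})

test_that("credibility bands bracket the mean on every curve", {
  set.seed(19)
  dr <- zero_draws(9, 100)
  dr[, "alpha"] <- rnorm(100, 0.5, 0.15)
  for (c in grep("^lambda_", colnames(dr))) dr[, c] <- rnorm(100, 0, 0.1)
  fit <- make_stub_fit(9, dr)
  cur <- hourly_curve(fit, season = "es")
  expect_true(all(cur$ci_low <= cur$mean_rate + 1e-12))
  expect_true(all(cur$mean_rate <= cur$ci_high + 1e-12))
  expect_true(all(cur$ci_low >= 0))
})
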