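test_that("circular hour distance wraps the 24-hour clock", {
  expect_identical(circ_hour_dist(24, 1), 1L)
  expect_identical(circ_hour_dist(5, 5), 0L)
  expect_identical(circ_hour_dist(1, 13), 12L)
  # brute force over both path directions, all pairs
  for (i in 1:24) for (j in 1:24) {
    expect_identical(circ_hour_dist(i, j),
                     min(abs(i - j), 24L - abs(i - j)))
    expect_identical(circ_hour_dist(i, j), circ_hour_dist(j, i))
  }
  expect_true(all(outer(1:24, 1:24, circ_hour_dist) <= 12L))
  expect_error(circ_hour_dist(0, 5), "1..24")
  expect_error(circ_hour_dist(3, 25), "1..24")
})

test_that("cyclic covariance has the exponential-decay circulant structure", {
  cv <- hour_covariance(nu = 3, psi = 1)
  expect_equal(diag(cv$Sigma), rep(1, 24))
  expect_equal(cv$Sigma[1, 2], exp(-3), tolerance = 1e-12)
  expect_equal(cv$Sigma[1, 24], exp(-3), tolerance = 1e-12)

  cv2 <- hour_covariance(nu = 0.4, psi = 2.5)
  expect_equal(diag(cv2$Sigma), rep(1 / 2.5, 24))
  expect_equal(cv2$Sigma, t(cv2$Sigma))
  # circulant: every row is a rotation of the first
  for (i in 2:24) {
    expect_equal(cv2$Sigma[i, ], cv2$Sigma[1, c((24 - i + 2):24, 1:(24 - i + 1))],
                 tolerance = 1e-12)
  }
  expect_true(all(eigen(cv2$Sigma, symmetric = TRUE)$values > 0))
  # eigenvalues equal the DFT of the first row
  expect_equal(sort(Re(fft(cv2$Sigma[1, ]))),
               sort(eigen(cv2$Sigma, symmetric = TRUE)$values),
               tolerance = 1e-9)
  expect_error(hour_covariance(0, 1), "nu")
  expect_error(hour_covariance(1, -2), "psi")
})

test_that("spectral inverse of the cyclic covariance matches dense inversion", {
  set.seed(3)
  for (rep in 1:10) {
    nu <- runif(1, 3 / 24, 3); psi <- rgamma(1, 2, 1)
    cv <- hour_covariance(nu, psi)
    expect_equal(bearcadian:::hour_covariance_inverse(cv), solve(cv$Sigma),
                 tolerance = 1e-8)
  }
})

test_that("the registry reproduces all thirteen model formulas and K counts", {
  reg <- model_registry()
  expect_length(reg, 13)
  golden <- c(
    "lambda_i + omega_k",
    "lambda_i + omega_k + mu_s + gamma_r + beta_1*exp(-phi_1*x1) + beta_4*exp(-phi_4*x4)",
    "lambda_i + omega_k + mu_s + gamma_r + beta_2*exp(-phi_2*x2) + beta_3*exp(-phi_3*x3) + beta_4*exp(-phi_4*x4)",
    "lambda_irs + omega_k + mu_s + gamma_r + beta_1r*exp(-phi_1r*x1) + beta_4r*exp(-phi_4r*x4)",
    "lambda_irs + omega_k + mu_s + gamma_r + beta_2r*exp(-phi_2r*x2) + beta_3r*exp(-phi_3r*x3) + beta_4r*exp(-phi_4r*x4)",
    "lambda_irs + omega_k + xi_rs + beta_1*exp(-phi_1*x1) + beta_4*exp(-phi_4*x4)",
    "lambda_irs + omega_k + xi_rs + beta_2*exp(-phi_2*x2) + beta_3*exp(-phi_3*x3) + beta_4*exp(-phi_4*x4)",
    "lambda_irs + omega_k + xi_rs + beta_1r*exp(-phi_1r*x1) + beta_4r*exp(-phi_4r*x4)",
    "lambda_irs + omega_k + xi_rs + beta_2r*exp(-phi_2r*x2) + beta_3r*exp(-phi_3r*x3) + beta_4r*exp(-phi_4r*x4)",
    "lambda_ir + omega_k + gamma_r + beta_1*exp(-phi_1*x1) + beta_4*exp(-phi_4*x4)",
    "lambda_ir + omega_k + gamma_r + beta_2*exp(-phi_2*x2) + beta_3*exp(-phi_3*x3) + beta_4*exp(-phi_4*x4)",
    "lambda_ir + omega_k + gamma_r + beta_1r*exp(-phi_1r*x1) + beta_4r*exp(-phi_4r*x4)",
    "lambda_ir + omega_k + gamma_r + beta_2r*exp(-phi_2r*x2) + beta_3r*exp(-phi_3r*x3) + beta_4r*exp(-phi_4r*x4)")
  expect_identical(vapply(reg, render_formula, character(1)), golden)
  expect_identical(vapply(reg, bearcadian:::interaction_count, integer(1)),
                   c(0L, 0L, 0L, 3L, 4L, 2L, 2L, 4L, 5L, 1L, 1L, 3L, 4L))
  expect_error(model_spec(14), "1..13")

  tmp <- tempfile(fileext = ".json")
  registry_to_json(tmp)
  back <- registry_from_json(tmp)
  expect_identical(vapply(back, render_formula, character(1)), golden)
})

test_that("exponential distance decay behaves at zero, range and infinity", {
  expect_equal(anthropogenic_effect(0.4, 2, 0), 0.4)
  expect_equal(anthropogenic_effect(0.4, 2, 1e6), 0)
  expect_equal(anthropogenic_effect(0.4, 2, 3 / 2), 0.4 * exp(-3),
               tolerance = 1e-12)
  x <- seq(0, 4, by = 0.1)
  expect_true(all(diff(anthropogenic_effect(1, 0.9, x)) < 0))
  expect_error(anthropogenic_effect(1, -1, 1), "phi")
  expect_error(anthropogenic_effect(1, 1, -0.5), "distances")
})

test_that("the linear predictor assembles each registry formula", {
  # base model: Eq-2-style sum
  st1 <- diel_state(model_spec(1), n_animals = 1,
                    lambda = matrix(0.2, 24, 1), omega = 0.1)
  rec <- data.frame(hour_index = 7, season = 2, sex = 1, animal = 1,
                    x1 = 1, x2 = 1, x3 = 1, x4 = 1)
  expect_equal(linear_predictor(st1, rec, model_spec(1)), 0.3)

  # richest model with beta = 0 reduces to lambda + omega + xi
  st9 <- diel_state(model_spec(9), n_animals = 1,
                    lambda = matrix(0.3, 24, 8), omega = 0.1,
                    fixed = seq(0.01, 0.07, by = 0.01), beta = 0)
  rec$sex <- 2
  expect_equal(linear_predictor(st9, rec, model_spec(9)),
               0.3 + 0.1 + st9$fixed[["xi_es_M"]])

  # every model, random states and records, vs the term-by-term oracle
  set.seed(21)
  for (id in 1:13) {
    spec <- model_spec(id)
    nb <- length(bearcadian:::anthro_coef_names(spec, "beta"))
    st <- diel_state(spec, n_animals = 3,
                     lambda = matrix(rnorm(24 * ncol(diel_state(spec)$lambda)), 24),
                     omega = rnorm(3),
                     fixed = rnorm(length(bearcadian:::fixed_coef_names(spec))),
                     beta = if (nb) rnorm(nb) else numeric(0),
                     phi = if (nb) runif(nb, 0.75, 15) else numeric(0))
    recs <- data.frame(hour_index = sample(1:24, 20, TRUE),
                       season = sample(1:4, 20, TRUE),
                       sex = sample(1:2, 20, TRUE),
                       animal = sample(1:3, 20, TRUE),
                       x1 = runif(20, 0, 4), x2 = runif(20, 0, 4),
                       x3 = runif(20, 0, 4), x4 = runif(20, 0, 4))
    got <- linear_predictor(st, recs, spec)
    want <- vapply(seq_len(20), function(t) oracle_predictor(st, recs[t, ], spec),
                   numeric(1))
    expect_equal(got, want, tolerance = 1e-12, label = paste("model", id))
  }
})

test_that("the predictor is linear in each beta coefficient", {
  spec <- model_spec(9)
  rec <- data.frame(hour_index = 3, season = 1, sex = 1, animal = 1,
                    x1 = 0.5, x2 = 0.5, x3 = 1, x4 = 2)
  st <- diel_state(spec, n_animals = 1, beta = 0.2)
  base <- linear_predictor(st, rec, spec)
  st2 <- st; st2$beta[["beta_x2_sp"]] <- st$beta[["beta_x2_sp"]] + 1
  slope <- linear_predictor(st2, rec, spec) - base
  st3 <- st; st3$beta[["beta_x2_sp"]] <- st$beta[["beta_x2_sp"]] + 2
  expect_equal(linear_predictor(st3, rec, spec) - base, 2 * slope,
               tolerance = 1e-12)
  expect_equal(slope, exp(-st$phi[["phi_x2_sp"]] * 0.5), tolerance = 1e-12)
})

test_that("log likelihood is the sum of Gaussian log densities", {
  spec <- model_spec(1)
  st <- diel_state(spec, n_animals = 1, lambda = matrix(0.4, 24, 1),
                   sigma2 = 1)
  rec <- data.frame(hour_index = 5, season = 1, sex = 1, animal = 1,
                    y = 0.4, x1 = 1, x2 = 1, x3 = 1, x4 = 1)
  expect_equal(log_likelihood(st, rec, spec), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  rec2 <- rbind(rec, rec)
  expect_equal(log_likelihood(st, rec2, spec),
               2 * log_likelihood(st, rec, spec), tolerance = 1e-12)

  set.seed(4)
  st$sigma2 <- 0.3
  recs <- data.frame(hour_index = sample(1:24, 30, TRUE), season = 1, sex = 1,
                     animal = 1, y = rnorm(30, 0.4, 0.5),
                     x1 = 1, x2 = 1, x3 = 1, x4 = 1)
  mu <- linear_predictor(st, recs, spec)
  want <- sum(-0.5 * log(2 * pi * 0.3) - (recs$y - mu)^2 / (2 * 0.3))
  expect_equal(log_likelihood(st, recs, spec), want, tolerance = 1e-10)
})

test_that("log prior matches a term-by-term density oracle and its supports", {
  spec <- model_spec(9)
  pr <- diel_priors()
  st <- diel_state(spec, n_animals = 2)

  st_bad <- st; st_bad$phi[3] <- 20
  expect_identical(log_prior(st_bad, pr, spec), -Inf)
  st_bad2 <- st; st_bad2$nu <- 0.1
  expect_identical(log_prior(st_bad2, pr, spec), -Inf)

  set.seed(9)
  st <- diel_state(spec, n_animals = 2,
                   lambda = matrix(rnorm(24 * 8, 0, 0.3), 24, 8),
                   omega = rnorm(2, 0.5, 0.3), alpha = 0.5, rho2 = 0.2,
                   fixed = rnorm(7, 0, 0.2), beta = rnorm(12, 0, 0.2),
                   phi = runif(12, 0.75, 15), nu = 0.8, psi = 2.2,
                   sigma2 = 0.1)
  got <- log_prior(st, pr, spec)
  Sig <- hour_covariance(st$nu, st$psi)$Sigma
  mn <- function(v) -0.5 * (24 * log(2 * pi) + determinant(Sig)$modulus[1] +
                              drop(v %*% solve(Sig, v)))
  want <- dunif(st$nu, 3 / 24, 3, log = TRUE) +
    sum(dunif(st$phi, 0.75, 15, log = TRUE)) +
    dgamma(1 / st$rho2, 1, 1, log = TRUE) +
    dgamma(1 / st$sigma2, 1, 1, log = TRUE) +
    dgamma(st$psi, 1, 1, log = TRUE) +
    dnorm(st$alpha, 0, sqrt(1000), log = TRUE) +
    sum(dnorm(st$fixed, 0, sqrt(1000), log = TRUE)) +
    sum(dnorm(st$beta, 0, sqrt(1000), log = TRUE)) +
    sum(dnorm(st$omega, st$alpha, sqrt(st$rho2), log = TRUE)) +
    sum(vapply(1:8, function(c) mn(st$lambda[, c]), numeric(1)))
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("covariance limits: white hours at large nu, rigid curve at small nu", {
  big <- hour_covariance(50, 2)$Sigma
  expect_equal(big, diag(24) / 2, tolerance = 1e-10)
  small <- hour_covariance(1e-8, 2)$Sigma
  expect_equal(small, matrix(1 / 2, 24, 24), tolerance = 1e-6)
})
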