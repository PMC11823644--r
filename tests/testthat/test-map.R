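test_that("censored log-likelihood matches the normal CDF, tails included", {
  expect_equal(bloq_loglik(pred = 0.4, loq = 0.4, sigma = 0.1), log(0.5))
  expect_equal(bloq_loglik(pred = 0.3, loq = 0.4, sigma = 0.1),
               log(pnorm(1)))
  expect_equal(bloq_loglik(pred = 0.3, loq = 0.4, sigma = 0.1),
               -0.1727, tolerance = 1e-3)
  # 10-sigma tail: finite and equal to the log-CDF, not log(underflow)
  deep <- bloq_loglik(pred = 0.4 + 10 * 0.1, loq = 0.4, sigma = 0.1)
  expect_true(is.finite(deep))
  expect_equal(deep, pnorm(-10, log.p = TRUE))
  expect_error(bloq_loglik(1, 0.4, 0), "positive")
})

test_that("the MAP objective reproduces hand arithmetic", {
  # one-eta model; observation engineered so the prediction at eta = 0.3 is
  # exactly 8 mg/L (independent closed-form inversion of the infusion
  # solution), obs = 10, sigma = 0.1 * 8 = 0.8
  m <- pk_model(1, c(CL = 6, V1 = 30), c(CL = 0.09),
                residual = list(prop = 0.1, add = 0))
  eta <- 0.3
  CL_i <- 6 * exp(eta); k <- CL_i / 30; tinf <- 0.5; t_obs <- 3
  D <- 8 * tinf * CL_i /
    ((1 - exp(-k * tinf)) * exp(-k * (t_obs - tinf)))
  reg <- pk_regimen(D, tinf = tinf)
  obs <- tibble::tibble(time = t_obs, dv = 10, bloq = FALSE, loq = 0.4)
  ofv1 <- map_objective(eta, m, list(), reg, obs, w = 1)
  expect_equal(ofv1, 0.3^2 / 0.09 + (10 - 8)^2 / 0.8^2 + log(0.8^2))
  expect_equal(ofv1, 6.8037, tolerance = 1e-4)
  # prior term is linear in w
  ofv05 <- map_objective(eta, m, list(), reg, obs, w = 0.5)
  expect_equal(ofv05, ofv1 - 0.5)
  expect_equal(ofv05, 6.3037, tolerance = 1e-4)
  # no data, eta = 0: both terms vanish
  expect_equal(map_objective(0, m, list(), reg, obs[0, ], w = 1), 0)
  expect_error(map_objective(eta, m, list(), reg, obs, w = 0), "0, 1")
  expect_error(map_objective(c(0, 0), m, list(), reg, obs, w = 1), "dimension")
})

test_that("the optimizer's fast objective equals the reference objective", {
  m <- two_cmt_model()
  covs <- list()
  reg <- pk_regimen(600, tinf = 0.5, ii = 24, n_doses = 2)
  obs <- tibble::tibble(time = c(1, 10, 26, 40),
                        dv = c(20, 3, 22, NA),
                        bloq = c(FALSE, FALSE, FALSE, TRUE),
                        loq = 0.4)
  fast <- tobramap:::.make_objective(m, covs, reg, obs, w = 0.7)
  withr::with_seed(11, {
    for (i in 1:20) {
      eta <- rnorm(2, 0, 0.4)
      expect_equal(fast(eta), map_objective(eta, m, covs, reg, obs, w = 0.7))
    }
  })
})

test_that("MAP fit returns the prior mode with no observations", {
  m <- two_cmt_model()
  reg <- pk_regimen(600, tinf = 0.5)
  fit <- map_fit(m, list(), reg, tibble::tibble(time = double(),
                                                dv = double(),
                                                bloq = logical()))
  expect_equal(unname(fit$eta), c(0, 0))
  expect_true(fit$converged)
  expect_equal(fit$n_obs_used, 0L)
  expect_equal(fit$params$CL, m$theta[["CL"]])
  # cut_time excludes everything -> same prior mode for every w
  obs <- tibble::tibble(time = c(1, 10), dv = c(20, 3), bloq = FALSE,
                        loq = 0.4)
  for (w in c(1, 0.5, 0.1)) {
    f <- map_fit(m, list(), reg, obs, w = w, cut_time = 0.5)
    expect_equal(unname(f$eta), c(0, 0))
  }
})

test_that("a one-eta fit matches a dense grid-search oracle", {
  m <- cl_only_model()
  reg <- pk_regimen(600, tinf = 0.5)
  t_obs <- 6; obs_val <- 6.5
  obs <- tibble::tibble(time = t_obs, dv = obs_val, bloq = FALSE, loq = 0.4)
  # oracle: closed-form prediction on a dense eta grid
  eta_grid <- seq(-2, 2, by = 5e-5)
  CL_g <- 6 * exp(eta_grid); k_g <- CL_g / 30
  pred_g <- (600 / (0.5 * CL_g)) * (1 - exp(-k_g * 0.5)) *
    exp(-k_g * (t_obs - 0.5))
  sd_g <- sqrt((0.1 * pred_g)^2 + 0.1^2)
  ofv_g <- eta_grid^2 / 0.09 + ((obs_val - pred_g) / sd_g)^2 + log(sd_g^2)
  eta_star <- eta_grid[which.min(ofv_g)]
  fit <- map_fit(m, list(), reg, obs, w = 1)
  expect_equal(unname(fit$eta), eta_star, tolerance = 1e-4)
})

test_that("rich noiseless data recover the true random effects", {
  # small assumed residual: with noiseless data the sigma(pred)-dependent
  # log-variance term would otherwise bias the optimum away from the truth
  m <- two_cmt_model(prop = 0.002, add = 0.002)
  reg <- pk_regimen(600, tinf = 0.5, ii = 24)
  eta_true <- c(CL = 0.25, V1 = -0.2)
  params <- individual_parameters(m, eta = eta_true)
  times <- seq(1, 23, by = 2)
  sim <- simulate_concentrations(params, reg, times)
  obs <- tibble::tibble(time = sim$time, dv = sim$conc, bloq = FALSE,
                        loq = 0.4)
  fit <- map_fit(m, list(), reg, obs, w = 1)
  expect_equal(unname(fit$eta), unname(eta_true), tolerance = 1e-3)
})

test_that("flattening the prior never worsens the data fit", {
  m <- two_cmt_model()
  reg <- pk_regimen(600, tinf = 0.5)
  omega_inv <- solve(m$omega)
  obs <- tibble::tibble(time = c(1, 10), dv = c(32, 1.8), bloq = FALSE,
                        loq = 0.4)
  data_fit <- function(w) {
    # data -2LL at the optimum: OFV minus the weighted prior quadratic form
    fit <- map_fit(m, list(), reg, obs, w = w)
    map_objective(fit$eta, m, list(), reg, obs, w = w) -
      w * drop(t(fit$eta) %*% omega_inv %*% fit$eta)
  }
  fits <- vapply(c(1, 0.75, 0.5, 0.25, 0.1), data_fit, 1)
  expect_true(all(diff(fits) <= 1e-8))
})

test_that("OFV is continuous across the censoring boundary", {
  # sweep a quantified observation toward the LOQ from above, then compare
  # with the censored version exactly at the LOQ: the likelihood definition
  # switches, but the optimized OFV must move continuously along the sweep
  m <- cl_only_model()
  reg <- pk_regimen(600, tinf = 0.5)
  loq <- 0.4
  dvs <- seq(0.42, 0.401, by = -0.001)
  ofvs <- vapply(dvs, function(v) {
    obs <- tibble::tibble(time = 22, dv = v, bloq = FALSE, loq = loq)
    map_fit(m, list(), reg, obs, w = 1)$ofv
  }, 1)
  expect_true(all(abs(diff(ofvs)) < 0.05))
  obs_cens <- tibble::tibble(time = 22, dv = NA_real_, bloq = TRUE, loq = loq)
  fit_cens <- map_fit(m, list(), reg, obs_cens, w = 1)
  expect_true(fit_cens$converged)
  expect_true(is.finite(fit_cens$ofv))
})

test_that("iterative forecasting respects chronology and information flow", {
  m <- two_cmt_model()
  reg <- pk_regimen(600, tinf = 0.5, ii = 24, n_doses = 3)
  obs3 <- tibble::tibble(
    time = c(1.5, 9.5, 25.5, 33.5, 49.5, 57.5),
    dv = c(18, 3, 19, 3.2, 18.5, 3.1), bloq = FALSE, loq = 0.4)
  fc <- iterative_forecast(m, list(), reg, obs3)
  expect_equal(unique(fc$group), 1:3)
  expect_equal(fc$mode[fc$group == 1], rep("a priori", 2))
  expect_true(all(fc$mode[fc$group > 1] == "a posteriori"))
  n_used <- tapply(fc$n_obs_used, fc$group, unique)
  expect_equal(as.vector(n_used, mode = "integer"), c(0L, 2L, 4L))
  # single group: a priori only
  fc1 <- iterative_forecast(m, list(), pk_regimen(600, tinf = 0.5),
                            tibble::tibble(time = c(1.5, 9.5),
                                           dv = c(18, 3), bloq = FALSE,
                                           loq = 0.4))
  expect_equal(unique(fc1$mode), "a priori")
})

test_that("a posteriori predictions beat a priori for an atypical individual", {
  m <- two_cmt_model()
  reg <- pk_regimen(600, tinf = 0.5, ii = 24, n_doses = 2)
  eta_true <- c(CL = 0.5, V1 = 0.3)
  params <- individual_parameters(m, eta = eta_true)
  times <- c(1.5, 9.5, 25.5, 33.5)
  sim <- simulate_concentrations(params, reg, times)
  obs <- tibble::tibble(time = sim$time, dv = sim$conc, bloq = FALSE,
                        loq = 0.4)
  fc <- iterative_forecast(m, list(), reg, obs)
  post_err <- sum((fc$pred[fc$group == 2] - fc$obs[fc$group == 2])^2)
  apriori <- tobramap:::.pred_obs(c(0, 0), m, list(), reg,
                                  obs$time[3:4])
  prior_err <- sum((apriori - obs$dv[3:4])^2)
  expect_lt(post_err, prior_err)
})

test_that("MAP exposure estimates round-trip and agree with quadrature", {
  m <- two_cmt_model(prop = 0.01, add = 0.01)
  reg <- pk_regimen(600, tinf = 0.5, ii = 24)
  eta_true <- c(CL = 0.2, V1 = -0.1)
  params <- individual_parameters(m, eta = eta_true)
  sim <- simulate_concentrations(params, reg, seq(1, 23, by = 2))
  obs <- tibble::tibble(time = sim$time, dv = sim$conc, bloq = FALSE,
                        loq = 0.4)
  fit <- map_fit(m, list(), reg, obs, w = 1)
  exposure <- estimate_exposure_map(fit, reg)
  true_auc <- compute_auc(params, reg, c(0, 24))
  expect_equal(exposure$auc, true_auc, tolerance = 5e-3)
  # AUC from fitted parameters equals trapezoid integration of its curve
  curve <- simulate_concentrations(fit$params, reg, seq(0, 24, by = 0.01))
  expect_equal(exposure$auc, compute_auc(curve, window = c(0, 24)),
               tolerance = 1e-3)
  # with zero observations the exposure is prior-driven and w-independent
  empty <- obs[0, ]
  aucs <- vapply(c(1, 0.5, 0.1), function(w) {
    estimate_exposure_map(map_fit(m, list(), reg, empty, w = w), reg)$auc
  }, 1)
  expect_equal(aucs, rep(aucs[1], 3))
})

test_that("eta_hat shrinks toward zero relative to the true variability", {
  m <- cl_only_model(prop = 0.15, add = 0.2)
  reg <- pk_regimen(600, tinf = 0.5)
  n <- 200
  withr::with_seed(42, {
    eta_true <- rnorm(n, 0, 0.3)
    eta_hat <- vapply(seq_len(n), function(i) {
      params <- individual_parameters(m, eta = c(CL = eta_true[i]))
      obs <- simulate_observations(params, reg, offsets = 6,
                                   residual = m$residual, seed = 1000 + i)
      if (obs$bloq[1]) return(0)
      map_fit(m, list(), reg, obs, w = 1)$eta[["CL"]]
    }, 1)
  })
  expect_lt(var(eta_hat), var(eta_true))
})
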