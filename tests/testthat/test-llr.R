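test_that("samples classify by offset from the end of infusion", {
  reg <- pk_regimen(600, tinf = 0.5, ii = 24, n_doses = 2)
  # offsets after end of infusion: 1.6 h (median peak time), 19.8 h (median
  # trough time), 3.5 h gap, during infusion
  cl <- classify_samples(
    tibble::tibble(time = 0.5 + c(1.6, 19.8, 3.5, -0.2)), reg)
  expect_equal(cl$kind, c("peak", "trough", "other", "invalid"))
  expect_equal(cl$offset_end, c(1.6, 19.8, 3.5, -0.2))
  # boundary: exactly 3 h is still a peak, exactly 4 h already a trough
  cl_b <- classify_samples(tibble::tibble(time = 0.5 + c(3, 4)), reg)
  expect_equal(cl_b$kind, c("peak", "trough"))
  # second interval anchors to the second dose
  cl2 <- classify_samples(tibble::tibble(time = 25.5), reg)
  expect_equal(cl2$dose_index, 2L)
  expect_equal(cl2$kind, "peak")
  expect_error(classify_samples(tibble::tibble(time = -1), reg), "after")
})

test_that("groups form within an interval and across exactly one dose", {
  reg <- pk_regimen(600, tinf = 0.5, ii = 24, n_doses = 3)
  obs <- tibble::tibble(
    time = c(1.5, 20, 23, 25.5, 44, 49.5),
    dv = c(18, 2, 1.5, 19, 2.2, 17), bloq = FALSE)
  cl <- classify_samples(obs, reg)
  g <- group_samples(cl, reg)
  expect_equal(nrow(g), 3L)
  expect_equal(g$configuration,
               c("peak-then-trough", "trough-dose-peak", "trough-dose-peak"))
  # non-overlapping: every observation in at most one group
  members <- c(g$obs1, g$obs2)
  expect_equal(anyDuplicated(members), 0L)
  # two troughs and no peak in an interval give no group
  obs2 <- tibble::tibble(time = c(6, 20), dv = c(5, 2), bloq = FALSE)
  g2 <- group_samples(classify_samples(obs2, pk_regimen(600, tinf = 0.5)),
                      pk_regimen(600, tinf = 0.5))
  expect_equal(nrow(g2), 0L)
})

test_that("the worked two-sample example reproduces the hand-derived fit", {
  # independent oracle: direct evaluation of the printed formulas
  C1 <- 8; C2 <- 2; t1 <- 1.5; t2 <- 9.5
  D <- 600; tinf <- 0.5; tau <- 24
  k_hand <- log(C1 / C2) / (t2 - t1)
  vd_hand <- D * (1 - exp(-k_hand * tinf)) * exp(-k_hand * (t1 - tinf)) /
    (tinf * k_hand * C1 * (1 - exp(-k_hand * tau)))
  reg <- pk_regimen(D, tinf = tinf, ii = tau)
  obs <- tibble::tibble(time = c(t1, t2), dv = c(C1, C2), bloq = FALSE)
  cl <- classify_samples(obs, reg)
  fit <- llr_fit(group_samples(cl, reg)[1, ], cl, reg)
  expect_equal(fit$k, k_hand)
  expect_equal(fit$Vd, vd_hand)
  expect_equal(fit$CL, k_hand * vd_hand)
  expect_equal(fit$k, 0.17329, tolerance = 1e-4)
  expect_equal(fit$Vd, 61.4, tolerance = 1e-3)
  expect_equal(fit$CL, 10.63, tolerance = 1e-3)
  expect_equal(llr_exposure(fit, daily_dose = 600)$auc24, 56.4,
               tolerance = 1e-3)
})

test_that("degenerate and censored groups report machine-readable reasons", {
  reg <- pk_regimen(600, tinf = 0.5, ii = 24)
  mk <- function(dv, bloq = c(FALSE, FALSE)) {
    obs <- tibble::tibble(time = c(1.5, 9.5), dv = dv, bloq = bloq)
    cl <- classify_samples(obs, reg)
    llr_fit(group_samples(cl, reg)[1, ], cl, reg)
  }
  expect_equal(mk(c(5, 5))$reason, "nonpositive-k")
  expect_equal(mk(c(2, 8))$reason, "nonpositive-k")
  expect_equal(mk(c(NA, 2), bloq = c(TRUE, FALSE))$reason, "bloq-sample")
  expect_equal(mk(c(5, 5))$status, "not-evaluable")
  empty <- llr_fit(group_samples(classify_samples(
    tibble::tibble(time = 3.6, dv = 5, bloq = FALSE), reg), reg), NULL, reg)
  expect_equal(empty$reason, "insufficient-samples")
})

test_that("noiseless steady-state samples are recovered exactly", {
  CL <- 5.2; V1 <- 26
  obs <- ss_two_samples(CL, V1, amt = 560, tinf = 0.5, ii = 24,
                        t_peak = 1.5, t_trough = 20)
  reg <- pk_regimen(560, tinf = 0.5, ii = 24, n_doses = 200)
  # classify against the last dose: use offsets-from-last-dose regimen
  reg1 <- pk_regimen(560, tinf = 0.5, ii = 24)
  cl <- classify_samples(obs, reg1)
  fit <- llr_fit(group_samples(cl, reg1)[1, ], cl, reg1)
  expect_equal(fit$k, CL / V1, tolerance = 1e-9)
  expect_equal(fit$Vd, V1, tolerance = 1e-6)
  expect_equal(fit$CL, CL, tolerance = 1e-6)
})

test_that("trough-dose-peak fits agree with the periodicity convention", {
  CL <- 5.2; V1 <- 26; k <- CL / V1
  # steady state: trough 1 h before a dose, peak 1.5 h after it
  params <- pk_params(CL = CL, V1 = V1)
  reg_long <- pk_regimen(560, tinf = 0.5, ii = 24, n_doses = 200)
  t_dose <- reg_long$time[200]
  sim <- simulate_concentrations(params, reg_long,
                                 c(t_dose - 1, t_dose + 1.5))
  # express times relative to the first of a 2-dose window
  reg <- pk_regimen(560, tinf = 0.5, ii = 24, n_doses = 2)
  obs <- tibble::tibble(time = c(23, 25.5), dv = sim$conc, bloq = FALSE)
  cl <- classify_samples(obs, reg)
  g <- group_samples(cl, reg)
  expect_equal(g$configuration, "trough-dose-peak")
  fit <- llr_fit(g[1, ], cl, reg)
  expect_equal(fit$status, "evaluable")
  # decay time: tau - t_pk_offset + t_tr_offset_before_dose = 24 - 1.5 - 1
  expect_equal(fit$delta_t, 21.5)
  expect_equal(fit$k, k, tolerance = 1e-9)
  expect_equal(fit$Vd, V1, tolerance = 1e-6)
})

test_that("LLR estimates are scale-equivariant and time-shift invariant", {
  reg <- pk_regimen(600, tinf = 0.5, ii = 24)
  obs <- tibble::tibble(time = c(1.5, 9.5), dv = c(8, 2), bloq = FALSE)
  fit_of <- function(obs, reg) {
    cl <- classify_samples(obs, reg)
    llr_fit(group_samples(cl, reg)[1, ], cl, reg)
  }
  base <- fit_of(obs, reg)
  scaled <- fit_of(dplyr::mutate(obs, dv = 2 * dv), reg)
  expect_equal(scaled$k, base$k)
  expect_equal(scaled$Vd, base$Vd / 2)
  expect_equal(scaled$CL, base$CL / 2)
  expect_equal(llr_exposure(scaled, daily_dose = 600)$auc24,
               2 * llr_exposure(base, daily_dose = 600)$auc24)
  shifted <- fit_of(dplyr::mutate(obs, time = time + 7),
                    pk_regimen(600, time = 7, tinf = 0.5, ii = 24))
  expect_equal(shifted$k, base$k)
  expect_equal(shifted$Vd, base$Vd)
})

test_that("LLR exposure predictions are consistent with quadrature", {
  CL <- 5.2; V1 <- 26
  obs <- ss_two_samples(CL, V1, amt = 560, tinf = 0.5, ii = 24,
                        t_peak = 1.5, t_trough = 20)
  reg1 <- pk_regimen(560, tinf = 0.5, ii = 24)
  cl <- classify_samples(obs, reg1)
  fit <- llr_fit(group_samples(cl, reg1)[1, ], cl, reg1)
  exposure <- llr_exposure(fit, daily_dose = 560)
  # AUC24 = daily dose / CL should equal the steady-state interval integral
  params <- pk_params(CL = fit$CL, V1 = fit$Vd)
  reg_ss <- pk_regimen(560, tinf = 0.5, ii = 24, n_doses = 15)
  auc_num <- compute_auc(params, reg_ss, c(14 * 24, 15 * 24), dt = 0.005)
  expect_equal(exposure$auc24, auc_num, tolerance = 1e-3)
  expect_error(llr_exposure(structure(list(status = "not-evaluable"),
                                      class = "llr_fit")), "not-evaluable")
})

test_that("every course gets an estimate or a reason from llr_course", {
  reg <- pk_regimen(600, tinf = 0.5, ii = 24)
  good <- llr_course(tibble::tibble(time = c(1.5, 9.5), dv = c(8, 2),
                                    bloq = FALSE), reg)
  expect_equal(good$status, "evaluable")
  expect_false(is.na(good$auc24))
  gap <- llr_course(tibble::tibble(time = c(3.6, 3.9), dv = c(6, 5.8),
                                   bloq = FALSE), reg)
  expect_equal(gap$status, "not-evaluable")
  expect_equal(gap$reason, "mistimed")
  lone <- llr_course(tibble::tibble(time = 1.5, dv = 8, bloq = FALSE), reg)
  expect_equal(lone$reason, "insufficient-samples")
})
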