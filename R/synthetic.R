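#' Default virtual-patient covariate configuration
#'
#' Target marginals for an adult cystic-fibrosis population on intravenous
#' tobramycin: median and 5th/95th percentiles per continuous covariate
#' (drawn log-normal, independently) plus the male proportion and
#' plausibility bounds used to reject extreme draws.
#'
#' @return A list with elements `continuous` (tibble: covariate, median, p5,
#'   p95, lower, upper) and `male_prop`.
#' @export
covariate_defaults <- function() {
  list(
    continuous = tibble::tribble(
      ~covariate, ~median,  ~p5,   ~p95,  ~lower, ~upper,
      "AGE",        32.7,  22.2,   58.8,    18,     90,
      "WT",         58.2,  39.0,   90.9,    30,    150,
      "HT",        165.1, 149.9,  182.9,   130,    210,
      "SCR",        0.73,  0.38,   1.31,   0.2,      5,
      "CRCL",      113.1,  25.4,  251.3,    10,    500
    ),
    male_prop = 28 / 50
  )
}

# Log-normal (meanlog, sdlog) from a median and 5th-95th percentile span:
# the median fixes meanlog; sdlog matches the full p5-p95 log-span, which
# balances both tails when the reported gaps are asymmetric (fitting only
# the wider half-gap would badly overshoot the opposite percentile and,
# after plausibility truncation, bias the median).
.lnorm_from_quantiles <- function(median, p5, p95) {
  if (p95 <= p5) abort("Inconsistent percentile spec: p95 must exceed p5.")
  z95 <- qnorm(0.95)
  sdlog <- log(p95 / p5) / (2 * z95)
  c(meanlog = log(median), sdlog = sdlog)
}

#' Generate virtual patients
#'
#' Continuous covariates are drawn independently from log-normal marginals
#' fitted to (median, 5th-95th percentile) targets; sex is Bernoulli. Draws
#' outside the plausibility bounds are rejected and redrawn. Fully
#' deterministic under `seed`.
#'
#' @param n Number of patients.
#' @param config A [covariate_defaults()]-shaped list.
#' @param seed Integer seed.
#' @return Tibble with `patient_id`, `AGE` (years), `WT` (kg), `HT` (cm),
#'   `sex`, `SCR` (mg/dL), `CRCL` (mL/min).
#' @examples
#' generate_patients(3, seed = 1)
#' @export
generate_patients <- function(n, config = covariate_defaults(), seed = 1) {
  stopifnot(n >= 1)
  cc <- config$continuous
  withr::with_seed(seed, {
    draws <- lapply(seq_len(nrow(cc)), function(i) {
      par <- .lnorm_from_quantiles(cc$median[i], cc$p5[i], cc$p95[i])
      x <- rlnorm(n, par["meanlog"], par["sdlog"])
      bad <- which(x < cc$lower[i] | x > cc$upper[i])
      while (length(bad)) {
        x[bad] <- rlnorm(length(bad), par["meanlog"], par["sdlog"])
        bad <- bad[x[bad] < cc$lower[i] | x[bad] > cc$upper[i]]
      }
      x
    })
    names(draws) <- cc$covariate
    sex <- ifelse(rbinom(n, 1, config$male_prop) == 1, "male", "female")
  })
  tibble::tibble(
    patient_id = seq_len(n),
    AGE = draws$AGE, WT = draws$WT, HT = draws$HT,
    sex = sex, SCR = draws$SCR, CRCL = draws$CRCL
  )
}

#' Draw individual random effects for each patient
#'
#' Each patient yields `k_draws` separate virtual individuals by sampling
#' log-scale random effects from `MVN(0, Omega)` of the simulating model.
#'
#' @param patients Tibble from [generate_patients()].
#' @param model The simulating [pk_model()].
#' @param k_draws Draws per patient (default 5).
#' @param seed Integer seed.
#' @return `patients` replicated `k_draws` times with columns `draw`,
#'   `individual_id`, and `eta` (list-column of named vectors).
#' @export
draw_individuals <- function(patients, model, k_draws = 5, seed = 1) {
  stopifnot(k_draws >= 1)
  eta_names <- rownames(model$omega)
  n_total <- nrow(patients) * k_draws
  etas <- withr::with_seed(seed, {
    MASS::mvrnorm(n_total, mu = rep(0, length(eta_names)),
                  Sigma = model$omega)
  })
  if (is.null(dim(etas))) etas <- matrix(etas, ncol = length(eta_names))
  colnames(etas) <- eta_names
  out <- tidyr::expand_grid(
    patients,
    draw = seq_len(k_draws)
  )
  out$individual_id <- seq_len(n_total)
  out$eta <- lapply(seq_len(n_total), function(i) etas[i, ])
  out
}

#' Simulate noisy, LOQ-censored observations
#'
#' Observations follow the combined residual model
#' `obs = pred * (1 + CV * e1) + add * e2` with independent standard-normal
#' `e1`, `e2`. Values below the LOQ (or negative draws) are flagged BLOQ and
#' their value withheld.
#'
#' @param params Individual parameter tibble.
#' @param regimen A [pk_regimen()].
#' @param offsets Sampling design: times after dose start, h.
#' @param residual Residual model list (`prop`, `add`), typically the
#'   simulating model's.
#' @param loq Limit of quantification, mg/L (default 0.4).
#' @param seed Integer seed.
#' @return Observation tibble: `time`, `dv` (NA when censored), `bloq`,
#'   `loq`, `true_conc`.
#' @export
simulate_observations <- function(params, regimen, offsets, residual,
                                  loq = 0.4, seed = 1) {
  if (loq <= 0) abort("`loq` must be positive.")
  if (any(offsets <= 0)) abort("Design offsets must be positive.")
  offsets <- sort(offsets)
  times <- regimen$time[1] + offsets
  pred <- simulate_concentrations(params, regimen, times)$conc
  dv <- withr::with_seed(seed, {
    pred * (1 + residual$prop * rnorm(length(pred))) +
      residual$add * rnorm(length(pred))
  })
  bloq <- dv < loq
  tibble::tibble(
    time = times,
    dv = ifelse(bloq, NA_real_, dv),
    bloq = bloq,
    loq = loq,
    true_conc = pred
  )
}

#' Simulate a full virtual cohort
#'
#' Chains patient generation, random-effect draws, true kinetics (10 mg/kg
#' infused over 30 min by default), true exposure, and noisy censored
#' observations under each sampling design. This is the study-condition
#' generator behind [run_experiment()].
#'
#' @param model Simulating [pk_model()].
#' @param n_patients Number of virtual patients.
#' @param k_draws Random-effect draws per patient.
#' @param designs Named list of sampling designs (offset vectors, h after
#'   dose start), e.g. `list(two_sample = c(1, 10))`.
#' @param dose_per_kg mg/kg per dose (default 10).
#' @param tinf Infusion length, h (default 0.5).
#' @param ii Scheduled interval, h (default 24).
#' @param auc_window True-AUC window from dose start, h; `c(0, Inf)` gives
#'   the analytic total exposure.
#' @param loq LOQ, mg/L.
#' @param config Covariate configuration.
#' @param seed Integer seed controlling every random stage.
#' @return Tibble with one row per (individual, design): patient covariates,
#'   `eta`, `params`, `regimen`, `true_auc`, `design`, `obs` (list-columns).
#' @export
simulate_cohort <- function(model, n_patients, k_draws = 5,
                            designs = list(two_sample = c(1, 10)),
                            dose_per_kg = 10, tinf = 0.5, ii = 24,
                            auc_window = c(0, 24), loq = 0.4,
                            config = covariate_defaults(), seed = 1) {
  patients <- generate_patients(n_patients, config, seed = seed)
  indiv <- draw_individuals(patients, model, k_draws, seed = seed + 1L)
  base <- purrr::map_dfr(seq_len(nrow(indiv)), function(i) {
    row <- indiv[i, ]
    covs <- list(WT = row$WT, HT = row$HT, AGE = row$AGE,
                 SCR = row$SCR, CRCL = row$CRCL, SEX = row$sex)
    params <- individual_parameters(model, covs, row$eta[[1]])
    regimen <- pk_regimen(amt = dose_per_kg * row$WT, tinf = tinf, ii = ii)
    true_auc <- compute_auc(params, regimen, window = auc_window)
    tibble::tibble(
      individual_id = row$individual_id, patient_id = row$patient_id,
      draw = row$draw,
      covariates = list(covs), eta = row$eta,
      params = list(params), regimen = list(regimen),
      true_auc = true_auc
    )
  })
  out <- tidyr::expand_grid(base, design = names(designs))
  out$obs <- purrr::map2(
    seq_len(nrow(out)), out$design,
    function(i, dsg) {
      simulate_observations(
        out$params[[i]], out$regimen[[i]], designs[[dsg]],
        residual = model$residual, loq = loq,
        seed = seed + 1000L + out$individual_id[i] * 10L +
          match(dsg, names(designs))
      )
    }
  )
  out
}
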