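#' Censored (below-LOQ) log-likelihood contribution — the M3 method
#'
#' A below-LOQ observation contributes the log-probability that the
#' measurement falls under the quantification limit given the model:
#' `ln Phi((loq - pred) / sigma)`. Evaluated through the normal log-CDF so
#' deep tails (predictions many sigma above the LOQ) stay finite instead of
#' underflowing to `log(0)`.
#'
#' @param pred Model-predicted concentration(s), mg/L.
#' @param loq Limit of quantification, mg/L.
#' @param sigma Residual SD at the prediction, mg/L (> 0).
#' @return Log-likelihood contribution(s), vectorized.
#' @examples
#' bloq_loglik(pred = 0.4, loq = 0.4, sigma = 0.1)  # log(0.5)
#' @export
bloq_loglik <- function(pred, loq, sigma) {
  if (any(sigma <= 0)) abort("`sigma` must be strictly positive.")
  pnorm((loq - pred) / sigma, log.p = TRUE)
}

# Residual SD at the model prediction: combined proportional + additive.
# Evaluating at the prediction (not the observation) is the M3-compatible
# convention; sigma(0) = additive SD guards the proportional term.
.res_sd <- function(pred, residual) {
  sqrt((residual$prop * pred)^2 + residual$add^2)
}

# Fast numeric objective closure for the optimizer. Mathematically
# identical to map_objective() (tested), but avoids per-evaluation tibble
# construction: covariate factors, the dose-time offset matrix and the
# omega inverse are precomputed once per fit.
.make_objective <- function(model, covariates, regimen, obs, w) {
  theta <- model$theta
  rel <- model$covariates
  for (i in seq_len(nrow(rel))) {
    x <- covariates[[rel$covariate[i]]]
    if (is.null(x)) {
      abort(paste0("Missing covariate `", rel$covariate[i], "`."))
    }
    fac <- switch(rel$form[i],
      "power-normalized"  = (x / rel$ref[i])^rel$coef[i],
      "linear-normalized" = 1 + rel$coef[i] * (x - rel$ref[i]) / rel$ref[i]
    )
    theta[rel$parameter[i]] <- theta[rel$parameter[i]] * fac
  }
  eta_names <- rownames(model$omega)
  omega_inv <- solve(model$omega)
  two_cmt <- model$n_compartments == 2L
  # n_obs x n_doses matrices of time offsets
  dt <- outer(obs$time, regimen$time, "-")
  amt <- regimen$amt
  tinf <- regimen$tinf
  prop <- model$residual$prop
  add <- model$residual$add
  bloq <- if ("bloq" %in% names(obs)) obs$bloq else rep(FALSE, nrow(obs))
  dv <- obs$dv
  loq <- obs$loq
  dt_inf <- pmax(pmin(dt, rep(tinf, each = nrow(dt))), 0)
  dt_post <- pmax(dt - rep(tinf, each = nrow(dt)), 0)
  active <- dt > 0
  scale <- rep(amt / tinf, each = nrow(dt))

  function(eta) {
    pars <- theta
    pars[eta_names] <- pars[eta_names] * exp(eta)
    CL <- pars[["CL"]]; V1 <- pars[["V1"]]
    if (two_cmt) {
      k10 <- CL / V1; k12 <- pars[["Q"]] / V1; k21 <- pars[["Q"]] / pars[["V2"]]
      s <- k10 + k12 + k21
      disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
      lambda <- c((s + disc) / 2, (s - disc) / 2)
      cf <- c((lambda[1] - k21) / (lambda[1] - lambda[2]),
              (k21 - lambda[2]) / (lambda[1] - lambda[2]))
    } else {
      lambda <- CL / V1
      cf <- 1
    }
    acc <- 0
    for (j in seq_along(lambda)) {
      acc <- acc + (cf[j] / lambda[j]) *
        (1 - exp(-lambda[j] * dt_inf)) * exp(-lambda[j] * dt_post)
    }
    pred <- rowSums(scale * acc * active) / V1
    sd_p <- sqrt((prop * pred)^2 + add^2)
    val <- w * drop(t(eta) %*% omega_inv %*% eta)
    if (any(!bloq)) {
      r <- (dv[!bloq] - pred[!bloq]) / sd_p[!bloq]
      val <- val + sum(r^2 + log(sd_p[!bloq]^2))
    }
    if (any(bloq)) {
      val <- val - 2 * sum(pnorm((loq[bloq] - pred[bloq]) / sd_p[bloq],
                                 log.p = TRUE))
    }
    val
  }
}

# Predictions at observation times for a given eta.
.pred_obs <- function(eta, model, covariates, regimen, times) {
  params <- individual_parameters(model, covariates, eta)
  conc_sorted <- simulate_concentrations(params, regimen, times)$conc
  out <- numeric(length(times))
  out[order(times)] <- conc_sorted
  out
}

#' MAP objective function (-2 log posterior up to a constant)
#'
#' \deqn{OFV(\eta) = w\,\eta^\top \Omega^{-1} \eta
#'   + \sum_{quantified} \left[\frac{(obs - pred)^2}{\sigma(pred)^2}
#'     + \ln \sigma(pred)^2\right]
#'   - 2 \sum_{BLOQ} \ln \Phi\!\left(\frac{LOQ - pred}{\sigma(pred)}\right)}
#'
#' The prior weight `w` multiplies the prior quadratic form — flattening the
#' prior (equivalently inflating the random-effect covariance to `Omega/w`)
#' so observed data dominate as `w` decreases. `w = 1` is standard MAP
#' estimation.
#'
#' @param eta Log-scale random-effect vector (ordered as `model$omega`).
#' @param model A [pk_model()].
#' @param covariates Named covariate list for the individual.
#' @param regimen A [pk_regimen()].
#' @param obs Observation tibble with `time`, `dv`, `bloq`, and `loq` for
#'   censored rows.
#' @param w Prior weight in (0, 1].
#' @return Scalar objective value.
#' @export
map_objective <- function(eta, model, covariates, regimen, obs, w = 1) {
  if (w <= 0 || w > 1) abort("Prior weight `w` must lie in (0, 1].")
  omega <- model$omega
  if (length(eta) != nrow(omega)) {
    abort("`eta` length must match the omega dimension.")
  }
  omega_inv <- tryCatch(solve(omega), error = function(e) {
    abort("Omega is singular; cannot evaluate the MAP prior term.")
  })
  prior <- w * drop(t(eta) %*% omega_inv %*% eta)
  if (!nrow(obs)) return(prior)
  pred <- .pred_obs(eta, model, covariates, regimen, obs$time)
  if (any(!is.finite(pred))) abort("Non-finite model prediction.")
  sd_p <- .res_sd(pred, model$residual)
  bloq <- if ("bloq" %in% names(obs)) obs$bloq else rep(FALSE, nrow(obs))
  data_term <- 0
  if (any(!bloq)) {
    r <- (obs$dv[!bloq] - pred[!bloq]) / sd_p[!bloq]
    data_term <- data_term + sum(r^2 + log(sd_p[!bloq]^2))
  }
  if (any(bloq)) {
    loq <- obs$loq[bloq]
    data_term <- data_term - 2 * sum(bloq_loglik(pred[bloq], loq, sd_p[bloq]))
  }
  prior + data_term
}

#' MAP Bayesian estimation of individual random effects
#'
#' Minimizes [map_objective()] by quasi-Newton local search started from
#' `eta = 0` plus deterministic perturbed restarts (+/- one prior SD
#' patterns), keeping the best optimum. With no observations before
#' `cut_time` the prior mode `eta = 0` is returned without invoking the
#' optimizer. If no start converges the fit falls back to `eta = 0` with a
#' warning and `converged = FALSE`.
#'
#' @inheritParams map_objective
#' @param cut_time Only observations strictly before this time (h) inform
#'   the fit (default `Inf`: all).
#' @param n_restarts Number of perturbed starts beyond `eta = 0`.
#' @param ofv_tol Convergence tolerance on the objective.
#' @return An object of class `map_fit`: `eta` (named), `params` (individual
#'   parameter tibble), `ofv`, `converged`, `n_obs_used` (quantified + BLOQ),
#'   `w`. Use [tidy()] / [glance()] for tibble views.
#' @export
map_fit <- function(model, covariates, regimen, obs, w = 1,
                    cut_time = Inf, n_restarts = 4, ofv_tol = 1e-8) {
  eta_names <- rownames(model$omega)
  d <- length(eta_names)
  obs <- tibble::as_tibble(obs)
  if (nrow(obs) && "time" %in% names(obs)) obs <- obs[obs$time < cut_time, ]
  mk_fit <- function(eta, ofv, converged) {
    eta <- setNames(as.numeric(eta), eta_names)
    structure(list(
      eta = eta,
      params = individual_parameters(model, covariates, eta),
      ofv = ofv, converged = converged,
      n_obs_used = nrow(obs), w = w, model_label = model$label
    ), class = "map_fit")
  }
  if (!nrow(obs)) {
    return(mk_fit(rep(0, d), 0, TRUE))
  }
  obj <- .make_objective(model, covariates, regimen, obs, w)
  sds <- sqrt(diag(model$omega) / w)
  starts <- matrix(0, nrow = 1 + n_restarts, ncol = d)
  if (n_restarts > 0) {
    # deterministic +/- one prior-SD patterns, cycled over components
    pat <- list(rep(1, d), rep(-1, d),
                rep_len(c(1, -1), d), rep_len(c(-1, 1), d))
    for (r in seq_len(n_restarts)) {
      starts[1 + r, ] <- sds * pat[[1 + (r - 1) %% 4]]
    }
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      nlminb(starts[s, ], obj,
             control = list(rel.tol = ofv_tol, abs.tol = 0, iter.max = 500)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective - 0) best <- res
  }
  if (is.null(best)) {
    warn("MAP optimizer failed to converge from every start; returning the prior mode.")
    return(mk_fit(rep(0, d), obj(rep(0, d)), FALSE))
  }
  mk_fit(best$par, best$objective, best$convergence == 0)
}

#' @export
print.map_fit <- function(x, ...) {
  cat(sprintf("<map_fit> w = %.2f, n_obs = %d, OFV = %.4f%s\n",
              x$w, x$n_obs_used, x$ofv,
              if (x$converged) "" else " (NOT converged)"))
  cat("  eta:", paste(names(x$eta), round(x$eta, 4), sep = "=",
                      collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy map_fit
#' @export
tidy.map_fit <- function(x, ...) {
  tibble::tibble(term = names(x$eta), estimate = unname(x$eta))
}

#' @method glance map_fit
#' @export
glance.map_fit <- function(x, ...) {
  dplyr::bind_cols(
    dplyr::select(x$params, -"n_compartments"),
    tibble::tibble(ofv = x$ofv, converged = x$converged,
                   n_obs_used = x$n_obs_used, w = x$w)
  )
}

#' Iterative a-priori / a-posteriori concentration forecasting
#'
#' Mirrors bedside use of a Bayesian dosing tool: the first group of
#' concentrations is predicted from population parameters plus covariates
#' alone (a priori, `eta = 0`); each later group is predicted from a MAP fit
#' informed by all previously known concentrations (BLOQ ones included via
#' the M3 likelihood). Predictions never see same-group or future samples.
#'
#' Groups are the LLR peak-trough pairs from [group_samples()], with any
#' ungrouped samples appended as singleton groups, all ordered
#' chronologically.
#'
#' @inheritParams map_objective
#' @return A tibble with one row per observation: `group`, `mode`
#'   (`"a priori"` / `"a posteriori"`), `time`, `obs`, `bloq`, `pred`,
#'   `n_obs_used`, `w`.
#' @export
iterative_forecast <- function(model, covariates, regimen, obs, w = 1) {
  obs <- tibble::as_tibble(obs)
  if (!nrow(obs)) {
    return(tibble::tibble(group = integer(), mode = character(),
                          time = double(), obs = double(), bloq = logical(),
                          pred = double(), n_obs_used = integer(), w = double()))
  }
  cl <- classify_samples(obs, regimen)
  grp <- group_samples(cl, regimen)
  membership <- rep(NA_integer_, nrow(obs))
  if (nrow(grp)) {
    for (g in seq_len(nrow(grp))) {
      membership[c(grp$obs1[g], grp$obs2[g])] <- g
    }
  }
  # singleton groups for the ungrouped, then renumber chronologically
  next_id <- max(0L, membership, na.rm = TRUE)
  for (i in which(is.na(membership))) {
    next_id <- next_id + 1L
    membership[i] <- next_id
  }
  first_time <- tapply(obs$time, membership, min)
  order_map <- rank(first_time, ties.method = "first")
  membership <- order_map[as.character(membership)]
  bloq <- if ("bloq" %in% names(obs)) obs$bloq else rep(FALSE, nrow(obs))
  out <- vector("list", max(membership))
  for (g in sort(unique(membership))) {
    in_g <- membership == g
    prior_obs <- obs[membership < g, , drop = FALSE]
    if (g == 1 || !nrow(prior_obs)) {
      fit <- map_fit(model, covariates, regimen, prior_obs[0, ], w = w)
      mode <- "a priori"
    } else {
      fit <- map_fit(model, covariates, regimen, prior_obs, w = w)
      mode <- "a posteriori"
    }
    pred <- .pred_obs(fit$eta, model, covariates, regimen, obs$time[in_g])
    out[[g]] <- tibble::tibble(
      group = g, mode = mode, time = obs$time[in_g],
      obs = obs$dv[in_g], bloq = bloq[in_g], pred = pred,
      n_obs_used = fit$n_obs_used, w = w
    )
  }
  dplyr::bind_rows(out)
}

#' Exposure estimates from a MAP fit
#'
#' Computes AUC over a window plus steady-state peak and trough predictions
#' from the fitted individual parameters.
#'
#' @param fit A [map_fit()].
#' @param regimen A [pk_regimen()].
#' @param window AUC window (h), default the first 24 h.
#' @param peak_offset,trough_offset Offsets after dose start (h) for the
#'   steady-state peak/trough predictions.
#' @return Tibble with `auc`, `peak`, `trough`.
#' @export
estimate_exposure_map <- function(fit, regimen, window = c(0, 24),
                                  peak_offset = 1, trough_offset = 23.5) {
  stopifnot(inherits(fit, "map_fit"))
  params <- fit$params
  auc <- compute_auc(params, regimen, window = window)
  ss <- steady_state_conc(params, amt = regimen$amt[1],
                          tinf = regimen$tinf[1], ii = regimen$ii[1],
                          offsets = c(peak_offset, trough_offset))
  tibble::tibble(auc = auc, peak = ss$conc[1], trough = ss$conc[2])
}
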