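#' Classify tobramycin samples as peak, trough, or other
#'
#' Clinical timing rules: a sample drawn within 3 h of the end of the
#' anchoring infusion is a peak; one drawn 4 or more hours after the end of
#' the infusion is a trough; anything in the (3, 4) h gap is `other`. A
#' sample drawn during an infusion is flagged `invalid` — courses containing
#' one are excluded from analysis.
#'
#' @param obs Tibble of observations with at least `time` (h from first dose
#'   start); columns `dv`, `bloq`, `loq` are carried through if present.
#' @param regimen A [pk_regimen()] giving the dose history.
#' @return `obs` with added columns `dose_index` (latest dose at or before
#'   the sample), `offset` (h after that dose's start), `offset_end` (h after
#'   the end of that infusion) and `kind` (`peak`/`trough`/`other`/`invalid`).
#' @examples
#' reg <- pk_regimen(600, tinf = 0.5, ii = 24, n_doses = 2)
#' classify_samples(tibble::tibble(time = c(2.1, 20.3, 25.5)), reg)
#' @export
classify_samples <- function(obs, regimen) {
  obs <- tibble::as_tibble(obs)
  if (any(obs$time < min(regimen$time))) {
    abort("Every observation must fall after at least one dose.")
  }
  idx <- findInterval(obs$time, regimen$time)
  offset <- obs$time - regimen$time[idx]
  offset_end <- offset - regimen$tinf[idx]
  kind <- dplyr::case_when(
    offset_end <= 0 ~ "invalid",
    offset_end <= 3 ~ "peak",
    offset_end >= 4 ~ "trough",
    TRUE ~ "other"
  )
  dplyr::mutate(obs, dose_index = idx, offset = offset,
                offset_end = offset_end, kind = kind)
}

#' Form two-sample LLR groups
#'
#' Builds peak-trough pairs: a peak and a trough within one dosing interval
#' (configuration `peak-then-trough`), or a trough followed by exactly one
#' dose and then a peak (`trough-dose-peak`). Assignment is greedy in
#' chronological order and non-overlapping — each observation joins at most
#' one group. Below-LOQ samples are grouped by their timing; [llr_fit()]
#' then reports them as not evaluable.
#'
#' @param classified Output of [classify_samples()].
#' @param regimen The matching [pk_regimen()].
#' @return Tibble with one row per group: `group`, `configuration`,
#'   `anchor_dose` (index of the dose the peak follows), `obs1`, `obs2` (row
#'   indices into `classified`, in chronological order).
#' @export
group_samples <- function(classified, regimen) {
  n <- nrow(classified)
  used <- rep(FALSE, n)
  ord <- order(classified$time)
  rows <- list()
  for (i in ord) {
    if (used[i]) next
    ki <- classified$kind[i]
    partner <- NA_integer_
    config <- NA_character_
    if (ki == "peak") {
      cand <- which(!used & classified$kind == "trough" &
                      classified$dose_index == classified$dose_index[i] &
                      classified$time > classified$time[i])
      if (length(cand)) {
        partner <- cand[which.min(classified$time[cand])]
        config <- "peak-then-trough"
      }
    } else if (ki == "trough") {
      cand <- which(!used & classified$kind == "peak" &
                      classified$dose_index == classified$dose_index[i] + 1L &
                      classified$time > classified$time[i])
      if (length(cand)) {
        partner <- cand[which.min(classified$time[cand])]
        config <- "trough-dose-peak"
      }
    }
    if (!is.na(partner)) {
      used[c(i, partner)] <- TRUE
      anchor <- if (config == "peak-then-trough") {
        classified$dose_index[i]
      } else {
        classified$dose_index[partner]
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        configuration = config, anchor_dose = anchor,
        obs1 = i, obs2 = partner
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble::tibble(group = integer(), configuration = character(),
                          anchor_dose = integer(), obs1 = integer(),
                          obs2 = integer()))
  }
  dplyr::mutate(out, group = dplyr::row_number(), .before = 1)
}

#' Two-sample log-linear regression fit
#'
#' The clinical-standard estimator: from a peak `C1` (the earlier-phase,
#' higher sample) and a trough `C2`, with decay time `dt` between them,
#' \deqn{k = \ln(C_1/C_2) / \Delta t}
#' \deqn{V_d = \frac{D (1 - e^{-k t_{inf}}) e^{-k (t_1 - t_{inf})}}
#'            {t_{inf} \, k \, C_1 (1 - e^{-k \tau})}}
#' \deqn{CL = k V_d}
#' where `t1` is the peak time measured from the anchoring dose's start and
#' `tau` the dosing interval. For a `trough-dose-peak` group the pre-dose
#' trough is mapped one interval forward by steady-state periodicity, so the
#' decay time is `tau - t_peak_offset + t_trough_offset_before_dose`.
#'
#' @param group One row of [group_samples()] output.
#' @param classified The classified observation tibble the group indexes.
#' @param regimen The matching [pk_regimen()].
#' @return An object of class `llr_fit`: list with `k` (1/h), `Vd` (L), `CL`
#'   (L/h), `status` (`"evaluable"` or `"not-evaluable"`), `reason` (one of
#'   `bloq-sample`, `mistimed`, `insufficient-samples`, `nonpositive-k`, or
#'   `NA`), plus the timing context used. Use [tidy()] for a tibble row.
#' @examples
#' reg <- pk_regimen(600, tinf = 0.5, ii = 24)
#' obs <- tibble::tibble(time = c(1.5, 9.5), dv = c(8, 2), bloq = FALSE)
#' cl <- classify_samples(obs, reg)
#' fit <- llr_fit(group_samples(cl, reg)[1, ], cl, reg)
#' tidy(fit)
#' @export
llr_fit <- function(group, classified, regimen) {
  fail <- function(reason) {
    structure(list(k = NA_real_, Vd = NA_real_, CL = NA_real_,
                   status = "not-evaluable", reason = reason,
                   configuration = group$configuration %||% NA_character_),
              class = "llr_fit")
  }
  if (is.null(group) || !nrow(group)) return(fail("insufficient-samples"))
  o1 <- classified[group$obs1, ]
  o2 <- classified[group$obs2, ]
  if (isTRUE(o1$bloq) || isTRUE(o2$bloq)) return(fail("bloq-sample"))
  anchor <- regimen[group$anchor_dose, ]
  tinf <- anchor$tinf
  tau <- anchor$ii
  if (is.na(tau) || is.na(tinf)) return(fail("mistimed"))
  if (group$configuration == "peak-then-trough") {
    pk <- o1; tr <- o2
    t1 <- pk$offset
    delta_t <- tr$offset - pk$offset
  } else {
    tr <- o1; pk <- o2
    t1 <- pk$offset
    tr_off <- tr$time - anchor$time  # negative: before the anchoring dose
    delta_t <- tau + tr_off - t1
  }
  C1 <- pk$dv; C2 <- tr$dv
  if (is.na(C1) || is.na(C2)) return(fail("bloq-sample"))
  if (delta_t <= 0) return(fail("mistimed"))
  if (C1 <= C2) return(fail("nonpositive-k"))
  k <- log(C1 / C2) / delta_t
  Vd <- anchor$amt * (1 - exp(-k * tinf)) * exp(-k * (t1 - tinf)) /
    (tinf * k * C1 * (1 - exp(-k * tau)))
  structure(list(k = k, Vd = Vd, CL = k * Vd,
                 status = "evaluable", reason = NA_character_,
                 configuration = group$configuration,
                 D = anchor$amt, tinf = tinf, tau = tau, t1 = t1,
                 delta_t = delta_t, C1 = C1, C2 = C2),
            class = "llr_fit")
}

#' @export
print.llr_fit <- function(x, ...) {
  if (x$status == "evaluable") {
    cat(sprintf(
      "<llr_fit> k = %.5f 1/h, Vd = %.2f L, CL = %.3f L/h (%s)\n",
      x$k, x$Vd, x$CL, x$configuration))
  } else {
    cat("<llr_fit> not evaluable:", x$reason, "\n")
  }
  invisible(x)
}

#' @method tidy llr_fit
#' @export
tidy.llr_fit <- function(x, ...) {
  tibble::tibble(k = x$k, Vd = x$Vd, CL = x$CL,
                 status = x$status, reason = x$reason,
                 configuration = x$configuration)
}

#' @method glance llr_fit
#' @export
glance.llr_fit <- function(x, ...) {
  tibble::tibble(status = x$status, reason = x$reason,
                 evaluable = x$status == "evaluable")
}

#' Exposure and concentration predictions from an LLR fit
#'
#' The daily exposure is `AUC24 = daily dose / CL`; concentration
#' predictions come from the fitted one-compartment model at steady state.
#'
#' @param fit An evaluable [llr_fit()].
#' @param daily_dose Total dose per 24 h, mg. Defaults to the anchoring
#'   dose amount scaled to 24 h by the interval.
#' @param offsets Optional times after dose start (h) at which to predict
#'   steady-state concentrations.
#' @return List with `auc24` (mg*h/L) and, when `offsets` is given, a
#'   tibble `predicted` of steady-state concentrations.
#' @export
llr_exposure <- function(fit, daily_dose = NULL, offsets = NULL) {
  stopifnot(inherits(fit, "llr_fit"))
  if (fit$status != "evaluable") {
    abort("Cannot compute exposure from a not-evaluable LLR fit.")
  }
  if (is.null(daily_dose)) daily_dose <- fit$D * 24 / fit$tau
  out <- list(auc24 = daily_dose / fit$CL)
  if (!is.null(offsets)) {
    params <- pk_params(CL = fit$CL, V1 = fit$Vd)
    out$predicted <- steady_state_conc(params, amt = fit$D, tinf = fit$tinf,
                                       ii = fit$tau, offsets = offsets)
  }
  out
}

#' Run the full LLR pipeline on one course
#'
#' Classifies, groups, and fits every group of a course, returning one tidy
#' row per group (evaluable or not) so that every course gets either at
#' least one estimate or a machine-readable reason.
#'
#' @param obs Observation tibble (`time`, `dv`, `bloq`).
#' @param regimen A [pk_regimen()].
#' @return Tibble with columns `group`, `configuration`, `k`, `Vd`, `CL`,
#'   `auc24`, `status`, `reason`. A course with no groupable samples yields
#'   a single `not-evaluable` row with reason `insufficient-samples` (or
#'   `mistimed` when samples exist but none meet the peak/trough windows).
#' @export
llr_course <- function(obs, regimen) {
  cl <- classify_samples(obs, regimen)
  groups <- group_samples(cl, regimen)
  if (!nrow(groups)) {
    reason <- if (!nrow(cl)) {
      "insufficient-samples"
    } else if (any(cl$kind %in% c("peak", "trough"))) {
      "insufficient-samples"
    } else {
      "mistimed"
    }
    return(tibble::tibble(group = NA_integer_,
                          configuration = NA_character_,
                          k = NA_real_, Vd = NA_real_, CL = NA_real_,
                          auc24 = NA_real_, status = "not-evaluable",
                          reason = reason))
  }
  purrr::map_dfr(seq_len(nrow(groups)), function(g) {
    fit <- llr_fit(groups[g, ], cl, regimen)
    row <- tidy(fit)
    row$group <- groups$group[g]
    row$auc24 <- if (fit$status == "evaluable") llr_exposure(fit)$auc24 else NA_real_
    dplyr::select(row, "group", "configuration", "k", "Vd", "CL",
                  "auc24", "status", "reason")
  })
}
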