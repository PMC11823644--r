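#' Read / write NONMEM-convention longitudinal datasets
#'
#' The interchange format is a CSV with one row per event: `ID` (course),
#' `PTID` (patient), `TIME` (h), `EVID` (1 dose, 0 observation), `AMT` (mg),
#' `RATE` (mg/h), `DV` (mg/L), `MDV`, `BLQ`, `LLOQ` (mg/L), covariates
#' `WT`, `HT`, `AGE`, `SEX` (1 male / 0 female), `SCR`, `CRCL`, and an
#' optional `II` (h). Dose rows carry `AMT`/`RATE` (infusion length is
#' `AMT/RATE`); observation rows carry `DV`, or `BLQ = 1` with `MDV = 1` and
#' the value withheld. This follows the common M3 dataset idiom so real
#' clinical extracts can be adapted without code changes.
#'
#' @param path CSV file path.
#' @return A nested tibble with one row per course: `course_id`,
#'   `patient_id`, `covariates` (list), `regimen` (list of [pk_regimen()]
#'   tibbles), `obs` (list of observation tibbles).
#' @export
read_pk_dataset <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  mandatory <- c("ID", "PTID", "TIME", "EVID", "AMT", "RATE", "DV", "MDV",
                 "BLQ", "LLOQ", "WT", "HT", "AGE", "SEX", "SCR", "CRCL")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    abort(paste0("Dataset is missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- which(!raw$EVID %in% c(0, 1))
  if (length(bad)) {
    abort(paste0("Malformed EVID at data line(s) ",
                 paste(head(bad, 5), collapse = ", "), "."))
  }
  dataset_to_courses(raw)
}

#' @rdname read_pk_dataset
#' @param dataset A row-per-event tibble (e.g. from [courses_to_dataset()]).
#' @export
write_pk_dataset <- function(dataset, path) {
  readr::write_csv(dataset, path, progress = FALSE)
  invisible(path)
}

#' Convert between the row-per-event dataset and nested courses
#'
#' @param raw Row-per-event tibble with the [read_pk_dataset()] schema.
#' @return `dataset_to_courses()`: nested course tibble;
#'   `courses_to_dataset()`: row-per-event tibble.
#' @export
dataset_to_courses <- function(raw) {
  raw <- dplyr::arrange(raw, .data$ID, .data$TIME, dplyr::desc(.data$EVID))
  purrr::map_dfr(split(raw, raw$ID), function(rows) {
    doses <- rows[rows$EVID == 1, ]
    obs <- rows[rows$EVID == 0, ]
    if (nrow(obs) && nrow(doses) && any(obs$TIME < min(doses$TIME))) {
      warn(paste0("Course ", rows$ID[1],
                  ": observation before the first dose (retained)."))
    }
    ii <- if ("II" %in% names(doses) && any(!is.na(doses$II))) {
      doses$II
    } else if (nrow(doses) > 1) {
      rep(median(diff(doses$TIME)), nrow(doses))
    } else {
      rep(24, nrow(doses))
    }
    regimen <- tibble::tibble(
      time = doses$TIME, amt = doses$AMT,
      tinf = doses$AMT / doses$RATE, ii = as.numeric(ii)
    )
    bloq <- !is.na(rows$BLQ[rows$EVID == 0]) & obs$BLQ == 1
    tibble::tibble(
      course_id = rows$ID[1],
      patient_id = rows$PTID[1],
      covariates = list(list(WT = rows$WT[1], HT = rows$HT[1],
                             AGE = rows$AGE[1],
                             SEX = if (rows$SEX[1] == 1) "male" else "female",
                             SCR = rows$SCR[1], CRCL = rows$CRCL[1])),
      regimen = list(regimen),
      obs = list(tibble::tibble(
        time = obs$TIME,
        dv = ifelse(bloq, NA_real_, obs$DV),
        bloq = bloq,
        loq = obs$LLOQ
      ))
    )
  })
}

#' @rdname dataset_to_courses
#' @param courses Nested course tibble.
#' @export
courses_to_dataset <- function(courses) {
  purrr::map_dfr(seq_len(nrow(courses)), function(i) {
    cv <- courses$covariates[[i]]
    reg <- courses$regimen[[i]]
    obs <- courses$obs[[i]]
    base <- tibble::tibble(
      ID = courses$course_id[i], PTID = courses$patient_id[i],
      WT = cv$WT, HT = cv$HT, AGE = cv$AGE,
      SEX = if (identical(cv$SEX, "male")) 1 else 0,
      SCR = cv$SCR, CRCL = cv$CRCL
    )
    dose_rows <- dplyr::bind_cols(
      base[rep(1, nrow(reg)), ],
      tibble::tibble(TIME = reg$time, EVID = 1, AMT = reg$amt,
                     RATE = reg$amt / reg$tinf, DV = NA_real_, MDV = 1,
                     BLQ = 0, LLOQ = NA_real_, II = reg$ii)
    )
    obs_rows <- dplyr::bind_cols(
      base[rep(1, nrow(obs)), ],
      tibble::tibble(TIME = obs$time, EVID = 0, AMT = NA_real_,
                     RATE = NA_real_, DV = obs$dv,
                     MDV = as.integer(obs$bloq), BLQ = as.integer(obs$bloq),
                     LLOQ = obs$loq, II = NA_real_)
    )
    dplyr::arrange(dplyr::bind_rows(dose_rows, obs_rows),
                   .data$TIME, dplyr::desc(.data$EVID))
  })
}

#' Experiment configuration
#'
#' Bundles every knob of the simulation study: simulating model, estimating
#' model(s), prior weights, sampling designs, cohort size, residual/LOQ
#' settings, bootstrap depth, and the master seed.
#'
#' @param sim_model Simulating [pk_model()].
#' @param est_models Named list of estimating [pk_model()]s.
#' @param weights Prior weights in (0, 1].
#' @param designs Named list of sampling designs (offsets h after dose
#'   start). LLR is evaluated on every two-sample design.
#' @param n_patients,k_draws Cohort size: patients and random-effect draws
#'   per patient.
#' @param B Bootstrap replicates.
#' @param loq LOQ, mg/L.
#' @param dose_per_kg,tinf,ii Regimen: mg/kg per dose, infusion length (h),
#'   interval (h).
#' @param auc_window True/estimated AUC window (h from dose start).
#' @param n_restarts MAP optimizer perturbed restarts.
#' @param seed Master integer seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(sim_model, est_models,
                              weights = c(1, 0.75, 0.5, 0.25, 0.1),
                              designs = list(two_sample = c(1, 10)),
                              n_patients = 50, k_draws = 5, B = 1000,
                              loq = 0.4, dose_per_kg = 10, tinf = 0.5,
                              ii = 24, auc_window = c(0, 24),
                              n_restarts = 4, seed = 1) {
  stopifnot(inherits(sim_model, "pk_model"),
            all(vapply(est_models, inherits, TRUE, "pk_model")),
            length(designs) >= 1, !is.null(names(est_models)))
  if (any(weights <= 0 | weights > 1)) {
    abort("All prior weights must lie in (0, 1].")
  }
  structure(list(
    sim_model = sim_model, est_models = est_models, weights = weights,
    designs = designs, n_patients = n_patients, k_draws = k_draws, B = B,
    loq = loq, dose_per_kg = dose_per_kg, tinf = tinf, ii = ii,
    auc_window = auc_window, n_restarts = n_restarts, seed = as.integer(seed)
  ), class = "experiment_config")
}

#' Run the full estimator-comparison experiment
#'
#' Pipeline: generate virtual patients, draw individual kinetics (k draws
#' per patient), simulate true curves and true AUC, draw noisy censored
#' observations under each design, estimate AUC by two-sample LLR and by
#' MAP Bayesian estimation (every estimating model x prior weight x
#' design), then compute accuracy/MPE/nRMSE with patient-level bootstrap
#' intervals and interval-overlap comparisons against LLR. Fully
#' deterministic given the config (including its seed).
#'
#' @param config An [experiment_config()].
#' @param verbose Log stage progress via `message()`.
#' @return A `tobra_experiment` list: `config`, `truth` (per-individual true
#'   AUC and observations), `estimates` (long tibble of AUC estimates),
#'   `metrics` (bootstrap metric table), `comparisons` (verdicts vs LLR).
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(...)
  say("stage 1/4: simulating cohort (n = ", config$n_patients, " x ",
      config$k_draws, " draws)")
  cohort <- simulate_cohort(
    config$sim_model, config$n_patients, config$k_draws, config$designs,
    dose_per_kg = config$dose_per_kg, tinf = config$tinf, ii = config$ii,
    auc_window = config$auc_window, loq = config$loq, seed = config$seed
  )

  say("stage 2/4: LLR estimation")
  two_sample_designs <- names(config$designs)[
    vapply(config$designs, length, 1L) == 2
  ]
  llr_est <- purrr::map_dfr(
    which(cohort$design %in% two_sample_designs), function(i) {
      fits <- llr_course(cohort$obs[[i]], cohort$regimen[[i]])
      f1 <- fits[1, ]
      tibble::tibble(
        individual_id = cohort$individual_id[i],
        patient_id = cohort$patient_id[i],
        design = cohort$design[i],
        method = "llr", est_model = "llr", w = NA_real_,
        pred_auc = f1$auc24, status = f1$status, reason = f1$reason,
        true_auc = cohort$true_auc[i]
      )
    }
  )

  say("stage 3/4: MAP estimation (",
      length(config$est_models) * length(config$weights), " combos)")
  grid <- tidyr::expand_grid(
    est_model = names(config$est_models),
    w = config$weights
  )
  map_est <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    em <- config$est_models[[grid$est_model[g]]]
    purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
      fit <- map_fit(em, cohort$covariates[[i]], cohort$regimen[[i]],
                     cohort$obs[[i]], w = grid$w[g],
                     n_restarts = config$n_restarts)
      tibble::tibble(
        individual_id = cohort$individual_id[i],
        patient_id = cohort$patient_id[i],
        design = cohort$design[i],
        method = "map", est_model = grid$est_model[g], w = grid$w[g],
        pred_auc = compute_auc(fit$params, cohort$regimen[[i]],
                               window = config$auc_window),
        status = if (fit$converged) "evaluable" else "not-converged",
        reason = NA_character_,
        true_auc = cohort$true_auc[i]
      )
    })
  })
  estimates <- dplyr::bind_rows(llr_est, map_est)

  say("stage 4/4: metrics and bootstrap (B = ", config$B, ")")
  combos <- dplyr::distinct(estimates, .data$method, .data$est_model,
                            .data$w, .data$design)
  metrics <- purrr::map_dfr(seq_len(nrow(combos)), function(ci) {
    sub <- dplyr::semi_join(estimates, combos[ci, ],
                            by = c("method", "est_model", "w", "design"))
    pairs <- tibble::tibble(patient_id = sub$patient_id,
                            pred = sub$pred_auc, obs = sub$true_auc)
    pairs <- pairs[!is.na(pairs$pred), ]
    if (!nrow(pairs)) return(NULL)
    rp <- bootstrap_metrics(pairs, "auc", B = config$B,
                            seed = config$seed + 5000L + ci)
    dplyr::bind_cols(combos[rep(ci, nrow(rp)), ], tibble::as_tibble(rp))
  })

  comparisons <- NULL
  llr_rows <- which(combos$method == "llr")
  if (length(llr_rows)) {
    ref_combo <- combos[llr_rows[1], ]
    ref_sub <- dplyr::semi_join(estimates, ref_combo,
                                by = c("method", "est_model", "w", "design"))
    ref_pairs <- tibble::tibble(patient_id = ref_sub$patient_id,
                                pred = ref_sub$pred_auc,
                                obs = ref_sub$true_auc)
    ref_pairs <- ref_pairs[!is.na(ref_pairs$pred), ]
    ref_rep <- bootstrap_metrics(ref_pairs, "auc", B = config$B,
                                 seed = config$seed + 4999L)
    comparisons <- purrr::map_dfr(
      which(combos$method == "map"), function(ci) {
        sub <- dplyr::semi_join(estimates, combos[ci, ],
                                by = c("method", "est_model", "w", "design"))
        pairs <- tibble::tibble(patient_id = sub$patient_id,
                                pred = sub$pred_auc, obs = sub$true_auc)
        rp <- bootstrap_metrics(pairs, "auc", B = config$B,
                                seed = config$seed + 5000L + ci)
        cmp <- compare_methods(rp, ref_rep,
                               labels = c(paste0("map/", combos$est_model[ci],
                                                 "/w=", combos$w[ci]), "llr"))
        dplyr::bind_cols(combos[rep(ci, nrow(cmp)), ], cmp)
      }
    )
  }

  structure(list(config = config, truth = cohort, estimates = estimates,
                 metrics = metrics, comparisons = comparisons),
            class = "tobra_experiment")
}

#' @export
print.tobra_experiment <- function(x, ...) {
  cat("<tobra_experiment> ", nrow(x$truth), " individual-design rows, ",
      nrow(x$estimates), " estimates\n", sep = "")
  print(dplyr::select(x$metrics, "method", "est_model", "w", "design",
                      "metric", "estimate", "lo", "hi"), n = 20)
  invisible(x)
}

#' Replay a clinical dataset through both estimation methods
#'
#' Applies the inclusion rules (at least two doses and two concentrations;
#' no concentration drawn during an infusion), then runs LLR
#' grouping/fitting and MAP iterative forecasting on every included course.
#' LLR predicts each group's concentrations from the most recent evaluable
#' earlier group; the Bayesian method predicts a priori for the first group
#' and a posteriori afterwards.
#'
#' @param courses Nested course tibble from [read_pk_dataset()].
#' @param model Estimating [pk_model()].
#' @param weights Prior weights to evaluate.
#' @return List with `predictions` (long tibble: course, method, w, kind,
#'   mode, time, obs, bloq, pred), `metrics` (accuracy/MPE/nRMSE per method,
#'   weight and sample kind), and `evaluability` (one row per course:
#'   included or the exclusion/not-evaluable reason).
#' @export
replay_clinical <- function(courses, model, weights = 1) {
  evals <- list(); preds <- list()
  for (i in seq_len(nrow(courses))) {
    cid <- courses$course_id[i]
    reg <- courses$regimen[[i]]
    obs <- courses$obs[[i]]
    if (nrow(reg) < 2 || sum(!is.na(obs$dv) | obs$bloq) < 2) {
      evals[[length(evals) + 1]] <- tibble::tibble(
        course_id = cid, status = "excluded",
        reason = "insufficient-doses-or-samples")
      next
    }
    cl <- classify_samples(obs, reg)
    if (any(cl$kind == "invalid")) {
      evals[[length(evals) + 1]] <- tibble::tibble(
        course_id = cid, status = "excluded",
        reason = "concentration-during-infusion")
      next
    }
    # LLR: fit every group; predict group g from the latest earlier
    # evaluable fit.
    groups <- group_samples(cl, reg)
    llr_fits <- purrr::map(seq_len(nrow(groups)),
                           ~ llr_fit(groups[.x, ], cl, reg))
    n_eval <- sum(vapply(llr_fits, function(f) f$status == "evaluable", TRUE))
    llr_reason <- if (!nrow(groups)) {
      "mistimed"
    } else if (n_eval == 0) {
      llr_fits[[1]]$reason
    } else {
      NA_character_
    }
    evals[[length(evals) + 1]] <- tibble::tibble(
      course_id = cid, status = "included",
      reason = llr_reason)
    if (nrow(groups) >= 2) {
      for (g in 2:nrow(groups)) {
        prev <- which(vapply(llr_fits[seq_len(g - 1)],
                             function(f) f$status == "evaluable", TRUE))
        if (!length(prev)) next
        fit <- llr_fits[[max(prev)]]
        rows <- c(groups$obs1[g], groups$obs2[g])
        pred <- llr_exposure(fit, offsets = cl$offset[rows])$predicted$conc
        preds[[length(preds) + 1]] <- tibble::tibble(
          course_id = cid, method = "llr", w = NA_real_,
          kind = cl$kind[rows], mode = "a posteriori",
          time = cl$time[rows], obs = cl$dv[rows], bloq = cl$bloq[rows],
          pred = pred)
      }
    }
    for (w in weights) {
      fc <- iterative_forecast(model, courses$covariates[[i]], reg, obs, w = w)
      fc_cl <- classify_samples(dplyr::rename(fc, dv = "obs"), reg)
      preds[[length(preds) + 1]] <- tibble::tibble(
        course_id = cid, method = "map", w = w,
        kind = fc_cl$kind, mode = fc$mode, time = fc$time,
        obs = fc$obs, bloq = fc$bloq, pred = fc$pred)
    }
  }
  predictions <- dplyr::bind_rows(preds)
  metrics <- NULL
  if (nrow(predictions)) {
    metrics <- predictions |>
      dplyr::filter(.data$kind %in% c("peak", "trough")) |>
      dplyr::group_by(.data$method, .data$w, .data$kind) |>
      dplyr::group_modify(function(df, key) {
        quant <- df[!df$bloq, ]
        if (nrow(quant) < 1) return(tibble::tibble())
        em <- error_metrics(tibble::tibble(pred = quant$pred,
                                           obs = quant$obs))
        acc <- accuracy(
          tibble::tibble(pred = df$pred, obs = df$obs, bloq = df$bloq),
          metric_kind = key$kind)
        tibble::tibble(accuracy = acc, mpe = em$mpe, nrmse = em$nrmse,
                       n = nrow(df))
      }) |>
      dplyr::ungroup()
  }
  list(predictions = predictions, metrics = metrics,
       evaluability = dplyr::bind_rows(evals))
}
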