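#' Prediction error metrics
#'
#' \deqn{RMSE = \sqrt{\tfrac{1}{N}\sum_i (pred_i - obs_i)^2}}
#' \deqn{nRMSE = RMSE / \bar{obs} \times 100\%}
#' \deqn{MPE = \tfrac{1}{N}\sum_i \frac{pred_i - obs_i}{obs_i} \times 100\%}
#'
#' @param pairs Data frame with columns `pred` and `obs` (same units);
#'   every `obs` must be strictly positive.
#' @return One-row tibble: `rmse` (data units), `nrmse` (%), `mpe` (%), `n`.
#' @examples
#' error_metrics(tibble::tibble(pred = c(10, 20), obs = c(8, 25)))
#' @export
error_metrics <- function(pairs) {
  if (!nrow(pairs)) abort("Cannot compute metrics on an empty pair set.")
  if (any(pairs$obs <= 0)) {
    bad <- which(pairs$obs <= 0)[1]
    abort(paste0("Non-positive observed value in pair ", bad,
                 "; exclude BLOQ/zero observations first."))
  }
  err <- pairs$pred - pairs$obs
  rmse <- sqrt(mean(err^2))
  tibble::tibble(
    rmse = rmse,
    nrmse = 100 * rmse / mean(pairs$obs),
    mpe = 100 * mean(err / pairs$obs),
    n = nrow(pairs)
  )
}

#' Clinical accuracy of exposure predictions
#'
#' Per-metric tolerable-error rules: a peak or AUC prediction is accurate
#' when within 20% of the reference value (boundary inclusive); a trough
#' prediction is accurate when predicted and reference values fall on the
#' same side of 1 mg/L (exactly 1 mg/L counts as "above" for both).
#'
#' @param pairs Data frame with `pred`, `obs`, and a single `metric_kind`
#'   (`"peak"`, `"trough"`, or `"auc"`) either as a column or via the
#'   `metric_kind` argument. Trough pairs may carry `bloq` observations
#'   (`obs` NA, `bloq` TRUE): these count as reference "below 1 mg/L".
#' @param metric_kind Overrides/sets the metric kind for all pairs.
#' @return Percent of accurate pairs (scalar).
#' @export
accuracy <- function(pairs, metric_kind = NULL) {
  kind <- metric_kind %||%
    (if ("metric_kind" %in% names(pairs)) unique(pairs$metric_kind))
  if (length(kind) != 1) {
    abort("Mixed metric kinds; compute accuracy per kind.")
  }
  if (!kind %in% c("peak", "trough", "auc")) {
    abort("`metric_kind` must be peak, trough, or auc.")
  }
  if (!nrow(pairs)) abort("Cannot compute accuracy on an empty pair set.")
  if (kind %in% c("peak", "auc")) {
    acc <- abs(pairs$pred - pairs$obs) / pairs$obs <= 0.20
  } else {
    bloq <- if ("bloq" %in% names(pairs)) pairs$bloq else rep(FALSE, nrow(pairs))
    obs_above <- ifelse(bloq, FALSE, pairs$obs >= 1)
    acc <- (pairs$pred >= 1) == obs_above
  }
  100 * mean(acc)
}

.all_metrics <- function(pairs, kind) {
  quant <- if ("bloq" %in% names(pairs)) pairs[!pairs$bloq, ] else pairs
  em <- error_metrics(quant)
  tibble::tibble(
    metric = c("accuracy", "mpe", "nrmse"),
    value = c(accuracy(pairs, kind), em$mpe, em$nrmse)
  )
}

#' Patient-level bootstrap of performance metrics
#'
#' Resamples patients (each with all their prediction pairs) with
#' replacement `B` times, recomputes accuracy, MPE and nRMSE per replicate,
#' and reports empirical 2.5th-97.5th percentile intervals (type-7
#' quantiles). Overlap of these intervals between two methods drives the
#' significance verdict of [compare_methods()].
#'
#' @param pairs Data frame with `patient_id`, `pred`, `obs` (and optionally
#'   `bloq` for trough pairs).
#' @param metric_kind `"peak"`, `"trough"`, or `"auc"`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return A `metrics_report` tibble: `metric`, `estimate`, `lo`, `hi`,
#'   `n_pairs`, `n_patients`, with the patient universe kept as an
#'   attribute for comparability checks.
#' @export
bootstrap_metrics <- function(pairs, metric_kind, B = 1000, seed = 1) {
  stopifnot(B >= 1)
  pairs <- tibble::as_tibble(pairs)
  if (!"patient_id" %in% names(pairs)) {
    abort("`pairs` needs a `patient_id` column.")
  }
  ids <- unique(pairs$patient_id)
  if (length(ids) < 2) {
    warn("Single patient: bootstrap interval is degenerate.")
  }
  point <- .all_metrics(pairs, metric_kind)
  by_patient <- split(seq_len(nrow(pairs)), pairs$patient_id)
  reps <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      take <- sample(length(ids), length(ids), replace = TRUE)
      rows <- unlist(by_patient[take], use.names = FALSE)
      .all_metrics(pairs[rows, ], metric_kind)$value
    }, numeric(3))
  })
  qs <- apply(reps, 1, quantile, probs = c(0.025, 0.975), type = 7,
              names = FALSE)
  out <- tibble::tibble(
    metric = point$metric,
    estimate = point$value,
    lo = qs[1, ], hi = qs[2, ],
    n_pairs = nrow(pairs),
    n_patients = length(ids)
  )
  attr(out, "patients") <- sort(ids)
  attr(out, "metric_kind") <- metric_kind
  class(out) <- c("metrics_report", class(out))
  out
}

#' Compare two methods by bootstrap interval overlap
#'
#' For each metric the method with the better point estimate (higher
#' accuracy, smaller |MPE|, lower nRMSE) is "significantly better" when the
#' two bootstrap percentile intervals do not overlap, and "not statistically
#' distinguishable" otherwise. Both reports must come from the same patient
#' universe.
#'
#' @param report_a,report_b [bootstrap_metrics()] outputs.
#' @param labels Character(2) method labels.
#' @return Tibble: `metric`, point estimates, `better`, `verdict`.
#' @export
compare_methods <- function(report_a, report_b,
                            labels = c("method A", "method B")) {
  pa <- attr(report_a, "patients"); pb <- attr(report_b, "patients")
  if (!is.null(pa) && !is.null(pb) && !identical(pa, pb)) {
    abort("Reports were computed on different patient universes.")
  }
  purrr::map_dfr(seq_len(nrow(report_a)), function(i) {
    m <- report_a$metric[i]
    j <- which(report_b$metric == m)
    ea <- report_a$estimate[i]; eb <- report_b$estimate[j]
    better_a <- switch(m,
      accuracy = ea > eb,
      mpe = abs(ea) < abs(eb),
      nrmse = ea < eb,
      ea > eb
    )
    disjoint <- report_a$hi[i] < report_b$lo[j] ||
      report_b$hi[j] < report_a$lo[i]
    verdict <- if (ea == eb || !disjoint) {
      "not statistically distinguishable"
    } else {
      paste(labels[if (better_a) 1 else 2], "significantly better")
    }
    tibble::tibble(
      metric = m, estimate_a = ea, estimate_b = eb,
      better = if (ea == eb) "tie" else labels[if (better_a) 1 else 2],
      intervals_overlap = !disjoint, verdict = verdict
    )
  })
}
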