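#' Performance versus prior weight
#'
#' Accuracy, MPE and nRMSE of MAP AUC estimation as a function of the prior
#' weight, faceted by metric, with the matched/mis-specified contrast in
#' colour and the LLR point estimate as a dashed reference line. Ribbons
#' show the bootstrap 2.5th-97.5th percentile interval.
#'
#' @param experiment A [run_experiment()] result.
#' @param design Which sampling design to show (default: first two-sample
#'   design in the metrics table).
#' @return A ggplot object.
#' @export
plot_weight_sweep <- function(experiment, design = NULL) {
  metrics <- experiment$metrics
  sim_label <- experiment$config$sim_model$label
  matched_names <- names(which(vapply(
    experiment$config$est_models,
    function(m) identical(m$label, sim_label), TRUE
  )))
  map_m <- dplyr::filter(metrics, .data$method == "map")
  design <- design %||% map_m$design[1]
  map_m <- dplyr::filter(map_m, .data$design == !!design) |>
    dplyr::mutate(specification = ifelse(.data$est_model %in% matched_names,
                                         "matched", "mis-specified"))
  llr_m <- dplyr::filter(metrics, .data$method == "llr")
  p <- ggplot2::ggplot(map_m, ggplot2::aes(x = .data$w, y = .data$estimate,
                                           colour = .data$specification,
                                           fill = .data$specification)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "prior weight", y = NULL,
                  title = "AUC estimation vs prior weight",
                  subtitle = "dashed line: two-sample LLR") +
    ggplot2::theme_minimal()
  if (nrow(llr_m)) {
    p <- p + ggplot2::geom_hline(
      data = dplyr::select(llr_m, "metric", "estimate"),
      ggplot2::aes(yintercept = .data$estimate),
      linetype = "dashed", inherit.aes = FALSE)
  }
  p
}

#' Performance versus single-sample timing
#'
#' Accuracy, MPE and nRMSE of MAP AUC estimation for single-sample designs
#' plotted against the sample offset, with the LLR two-sample reference as
#' a dashed line.
#'
#' @param experiment A [run_experiment()] result whose config includes
#'   single-sample designs.
#' @param w Prior weight to display (default: smallest weight present).
#' @return A ggplot object.
#' @export
plot_design_sweep <- function(experiment, w = NULL) {
  offsets <- vapply(experiment$config$designs, function(d) {
    if (length(d) == 1) d else NA_real_
  }, 1)
  single <- tibble::tibble(design = names(offsets), offset = offsets) |>
    dplyr::filter(!is.na(.data$offset))
  if (!nrow(single)) abort("No single-sample designs in this experiment.")
  map_m <- dplyr::filter(experiment$metrics, .data$method == "map") |>
    dplyr::inner_join(single, by = "design")
  w <- w %||% min(map_m$w)
  map_m <- dplyr::filter(map_m, .data$w == !!w)
  llr_m <- dplyr::filter(experiment$metrics, .data$method == "llr")
  p <- ggplot2::ggplot(map_m, ggplot2::aes(x = .data$offset,
                                           y = .data$estimate,
                                           colour = .data$est_model,
                                           fill = .data$est_model)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "single sample time after dose start (h)", y = NULL,
                  title = paste0("AUC estimation vs sample time (w = ", w, ")"),
                  subtitle = "dashed line: two-sample LLR at 1 & 10 h") +
    ggplot2::theme_minimal()
  if (nrow(llr_m)) {
    p <- p + ggplot2::geom_hline(
      data = dplyr::select(llr_m, "metric", "estimate"),
      ggplot2::aes(yintercept = .data$estimate),
      linetype = "dashed", inherit.aes = FALSE)
  }
  p
}

#' @method autoplot tobra_experiment
#' @export
autoplot.tobra_experiment <- function(object, ...) {
  plot_weight_sweep(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Fitted curves versus observations for one individual
#'
#' Overlays the true simulated curve (when available), the observations,
#' and one or more fitted concentration-time curves — the visual contrast
#' between the LLR one-compartment fit and the Bayesian fit.
#'
#' @param model Estimating [pk_model()] (for MAP curves).
#' @param covariates Covariate list. @param regimen A [pk_regimen()].
#' @param obs Observation tibble.
#' @param fits Named list of fits (`llr_fit` or `map_fit` objects).
#' @param true_params Optional true parameter tibble for the gold curve.
#' @param t_max Plot horizon, h.
#' @return A ggplot object.
#' @export
plot_fits <- function(model, covariates, regimen, obs, fits = list(),
                      true_params = NULL, t_max = 24) {
  grid <- seq(0, t_max, by = 0.05)
  curves <- list()
  if (!is.null(true_params)) {
    curves[["true"]] <- simulate_concentrations(true_params, regimen, grid)
  }
  for (nm in names(fits)) {
    f <- fits[[nm]]
    params <- if (inherits(f, "map_fit")) {
      f$params
    } else if (inherits(f, "llr_fit") && f$status == "evaluable") {
      pk_params(CL = f$CL, V1 = f$Vd)
    } else {
      NULL
    }
    if (!is.null(params)) {
      curves[[nm]] <- simulate_concentrations(params, regimen, grid)
    }
  }
  cdf <- dplyr::bind_rows(curves, .id = "curve")
  ggplot2::ggplot(cdf, ggplot2::aes(x = .data$time, y = .data$conc,
                                    colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(x = .data$time, y = .data$dv),
                        inherit.aes = FALSE, shape = 16) +
    ggplot2::labs(x = "time (h)", y = "concentration (mg/L)") +
    ggplot2::theme_minimal()
}
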