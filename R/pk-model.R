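#' Define a population pharmacokinetic model
#'
#' A `pk_model` bundles everything needed to simulate and fit individual
#' tobramycin kinetics: the structural order (one or two disposition
#' compartments), typical (fixed-effect) parameter values at reference
#' covariates, the covariance of the log-scale inter-individual random
#' effects, a combined proportional + additive residual-error model, and
#' normalized covariate relations.
#'
#' Individual parameters follow the usual log-normal convention
#' `P_i = theta_P * f_cov(covariates) * exp(eta_P)`, where `f_cov` multiplies
#' one factor per covariate relation:
#' * `power-normalized`: `(cov / ref) ^ coef`
#' * `linear-normalized`: `1 + coef * (cov - ref) / ref`
#'
#' @param n_compartments Integer, 1 or 2.
#' @param theta Named list or vector of typical values: `CL` (L/h), `V1` (L),
#'   and for two compartments also `Q` (L/h) and `V2` (L).
#' @param omega Covariance matrix of the log-scale random effects (variance
#'   units). Row/column names select which parameters carry inter-individual
#'   variability; they must be a subset of the theta names. A named numeric
#'   vector is taken as a diagonal.
#' @param residual List with elements `prop` (proportional CV, fraction) and
#'   `add` (additive SD, mg/L).
#' @param covariates Data frame of covariate relations with columns
#'   `parameter`, `covariate`, `form` (`"power-normalized"` or
#'   `"linear-normalized"`), `coef`, `ref`. May be `NULL` for none.
#' @param label Free-text model label.
#'
#' @return An object of class `pk_model`.
#' @examples
#' m <- pk_model(
#'   n_compartments = 1,
#'   theta = c(CL = 6, V1 = 30),
#'   omega = c(CL = 0.09, V1 = 0.04),
#'   residual = list(prop = 0.1, add = 0.2)
#' )
#' m
#' @export
pk_model <- function(n_compartments, theta, omega, residual,
                     covariates = NULL, label = "unnamed model") {
  if (!n_compartments %in% c(1L, 2L)) {
    abort("`n_compartments` must be 1 or 2.")
  }
  theta <- unlist(theta)
  need <- if (n_compartments == 2) c("CL", "V1", "Q", "V2") else c("CL", "V1")
  if (!all(need %in% names(theta))) {
    abort(paste0("`theta` must name ", paste(need, collapse = ", "), "."))
  }
  theta <- theta[need]
  if (any(!is.finite(theta)) || any(theta <= 0)) {
    abort("All theta values must be finite and strictly positive.")
  }
  if (is.null(dim(omega))) {
    if (is.null(names(omega))) abort("A vector `omega` must be named.")
    omega <- diag(omega, nrow = length(omega)) |>
      `dimnames<-`(list(names(omega), names(omega)))
  }
  if (is.null(rownames(omega)) || !all(rownames(omega) %in% names(theta))) {
    abort("`omega` dimnames must be a subset of the theta parameter names.")
  }
  if (!isTRUE(all.equal(omega, t(omega), tolerance = 1e-8))) {
    abort("`omega` must be symmetric.")
  }
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10 * max(abs(ev), 1))) {
    abort("`omega` must be positive semi-definite.")
  }
  if (is.null(residual$prop) || is.null(residual$add) ||
      residual$prop < 0 || residual$add < 0) {
    abort("`residual` needs non-negative elements `prop` and `add`.")
  }
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    need_cols <- c("parameter", "covariate", "form", "coef", "ref")
    if (!all(need_cols %in% names(covariates))) {
      abort(paste0("`covariates` needs columns ",
                   paste(need_cols, collapse = ", "), "."))
    }
    bad <- setdiff(covariates$form, c("power-normalized", "linear-normalized"))
    if (length(bad)) {
      abort(paste0("Unknown covariate relation form: ",
                   paste(bad, collapse = ", ")))
    }
  } else {
    covariates <- tibble::tibble(
      parameter = character(), covariate = character(), form = character(),
      coef = double(), ref = double()
    )
  }
  structure(
    list(
      n_compartments = as.integer(n_compartments),
      theta = theta,
      omega = omega,
      residual = list(prop = residual$prop, add = residual$add),
      covariates = covariates,
      label = label
    ),
    class = "pk_model"
  )
}

#' @export
print.pk_model <- function(x, ...) {
  cat("<pk_model> ", x$label, "\n", sep = "")
  cat("  compartments:", x$n_compartments, "\n")
  cat("  theta:", paste(names(x$theta), signif(x$theta, 4),
                        sep = "=", collapse = ", "), "\n")
  cat("  IIV on:", paste(rownames(x$omega), collapse = ", "),
      sprintf(" (CV%% ~ %s)",
              paste(round(100 * sqrt(diag(x$omega)), 1), collapse = ", ")),
      "\n")
  cat(sprintf("  residual: %.1f%% proportional + %.2f mg/L additive\n",
              100 * x$residual$prop, x$residual$add))
  if (nrow(x$covariates)) {
    cat("  covariates:",
        paste(x$covariates$parameter, x$covariates$covariate, sep = "~",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read / write a pk_model as a YAML configuration file
#'
#' The on-disk layout uses keys `model.compartments`, `model.theta.*`,
#' `model.omega` (column-major lower triangle), `model.sigma.{prop,add}` and
#' `model.covariates[]`, so model priors stay editable configuration rather
#' than code.
#'
#' @param path File path.
#' @param model A `pk_model`.
#' @return `read_pk_model()` returns a `pk_model`; `write_pk_model()` returns
#'   `path` invisibly.
#' @export
read_pk_model <- function(path) {
  cfg <- yaml::read_yaml(path)$model
  if (is.null(cfg)) abort("Config file has no top-level `model` key.")
  eta_names <- cfg$omega_names %||% names(cfg$theta)
  d <- length(eta_names)
  om <- matrix(0, d, d, dimnames = list(eta_names, eta_names))
  lt <- unlist(cfg$omega)
  om[lower.tri(om, diag = TRUE)] <- lt
  om <- om + t(om) - diag(diag(om), d)
  cov_tbl <- NULL
  if (length(cfg$covariates)) {
    cov_tbl <- purrr::map_dfr(cfg$covariates, tibble::as_tibble)
  }
  pk_model(
    n_compartments = cfg$compartments,
    theta = unlist(cfg$theta),
    omega = om,
    residual = list(prop = cfg$sigma$prop, add = cfg$sigma$add),
    covariates = cov_tbl,
    label = cfg$label %||% basename(path)
  )
}

#' @rdname read_pk_model
#' @export
write_pk_model <- function(model, path) {
  om <- model$omega
  yaml::write_yaml(list(model = list(
    label = model$label,
    compartments = model$n_compartments,
    theta = as.list(model$theta),
    omega_names = rownames(om),
    omega = as.list(om[lower.tri(om, diag = TRUE)]),
    sigma = model$residual,
    covariates = purrr::transpose(as.list(model$covariates))
  )), path)
  invisible(path)
}

#' Bundled illustrative tobramycin models
#'
#' Loads one of the two synthetic two-compartment tobramycin models shipped
#' with the package (`"hennig_like"`, `"alghanem_like"`). Their parameter
#' values are illustrative stand-ins chosen to be realistic for adults with
#' cystic fibrosis — they are NOT the published Hennig or Alghanem estimates,
#' which users should transcribe into the YAML configs if they hold them.
#' The two models deliberately differ (typical values, number of variability
#' terms, residual magnitude) so that matched versus mis-specified estimation
#' contrasts are meaningful.
#'
#' @param name `"hennig_like"` or `"alghanem_like"`.
#' @return A `pk_model`.
#' @export
example_model <- function(name = c("hennig_like", "alghanem_like")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("model_", name, "_synthetic.yaml"),
                      package = "tobramap", mustWork = TRUE)
  read_pk_model(path)
}

#' Individual PK parameters from covariates and random effects
#'
#' Applies the covariate model and the log-normal random effects to the
#' typical values: `P_i = theta_P * f_cov * exp(eta_P)`.
#'
#' @param model A [pk_model()].
#' @param covariates Named list (or one-row data frame) supplying every
#'   covariate named in the model's covariate relations.
#' @param eta Numeric vector of log-scale random effects, either named by
#'   parameter or ordered as the rows of `model$omega`. Defaults to all zero
#'   (the covariate-typical individual).
#' @return A one-row tibble with columns `CL`, `V1` (and `Q`, `V2` for a
#'   two-compartment model), the derived elimination coefficient
#'   `k = CL/V1`, and `n_compartments`.
#' @examples
#' m <- example_model("hennig_like")
#' individual_parameters(m, covariates = list(WT = 70, CRCL = 100))
#' @export
individual_parameters <- function(model, covariates = list(), eta = NULL) {
  stopifnot(inherits(model, "pk_model"))
  covariates <- as.list(covariates)
  eta_names <- rownames(model$omega)
  if (is.null(eta)) eta <- setNames(rep(0, length(eta_names)), eta_names)
  if (is.null(names(eta))) {
    if (length(eta) != length(eta_names)) {
      abort("`eta` length must match the omega dimension.")
    }
    names(eta) <- eta_names
  }
  pars <- model$theta
  rel <- model$covariates
  for (i in seq_len(nrow(rel))) {
    cov_name <- rel$covariate[i]
    if (is.null(covariates[[cov_name]])) {
      abort(paste0("Missing covariate `", cov_name, "` required by the ",
                   rel$parameter[i], " relation."))
    }
    x <- covariates[[cov_name]]
    fac <- switch(rel$form[i],
      "power-normalized"  = (x / rel$ref[i])^rel$coef[i],
      "linear-normalized" = 1 + rel$coef[i] * (x - rel$ref[i]) / rel$ref[i]
    )
    pars[rel$parameter[i]] <- pars[rel$parameter[i]] * fac
  }
  pars[names(eta)] <- pars[names(eta)] * exp(eta)
  if (any(!is.finite(pars)) || any(pars <= 0)) {
    abort("Covariate model produced a non-positive PK parameter.")
  }
  out <- tibble::as_tibble(as.list(pars))
  out$k <- out$CL / out$V1
  out$n_compartments <- model$n_compartments
  out
}

#' Construct PK parameters directly
#'
#' Convenience constructor for the parameter tibble consumed by
#' [simulate_concentrations()] and [compute_auc()], for use outside a
#' population model.
#'
#' @param CL Clearance, L/h. @param V1 Central volume, L.
#' @param Q Inter-compartmental clearance, L/h (two-compartment only).
#' @param V2 Peripheral volume, L (two-compartment only).
#' @return One-row parameter tibble.
#' @export
pk_params <- function(CL, V1, Q = NULL, V2 = NULL) {
  two <- !is.null(Q) || !is.null(V2)
  if (two && (is.null(Q) || is.null(V2))) {
    abort("Supply both `Q` and `V2` for a two-compartment parameter set.")
  }
  vals <- c(CL = CL, V1 = V1, if (two) c(Q = Q, V2 = V2))
  if (any(vals <= 0)) abort("PK parameters must be strictly positive.")
  out <- tibble::as_tibble(as.list(vals))
  out$k <- CL / V1
  out$n_compartments <- if (two) 2L else 1L
  out
}

#' Cockcroft-Gault creatinine clearance
#'
#' Optional helper for sites whose extracts carry serum creatinine only.
#' `CrCl = (140 - age) * weight / (72 * SCr)`, multiplied by 0.85 for
#' females. The simulator and models otherwise consume creatinine clearance
#' as a direct covariate.
#'
#' @param age Years. @param weight kg. @param scr Serum creatinine, mg/dL.
#' @param sex `"male"` or `"female"` (vectorized).
#' @return Creatinine clearance in mL/min.
#' @export
cockcroft_gault <- function(age, weight, scr, sex) {
  stopifnot(all(sex %in% c("male", "female")))
  crcl <- (140 - age) * weight / (72 * scr)
  crcl * ifelse(sex == "female", 0.85, 1)
}
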