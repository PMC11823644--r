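# Shared fixtures: small models and simulated courses, all built in code.

one_cmt_model <- function(prop = 0.1, add = 0.2, omega_cl = 0.09,
                          omega_v = 0.04) {
  pk_model(
    n_compartments = 1,
    theta = c(CL = 6, V1 = 30),
    omega = c(CL = omega_cl, V1 = omega_v),
    residual = list(prop = prop, add = add),
    label = "test 1-cmt"
  )
}

two_cmt_model <- function(prop = 0.1, add = 0.2) {
  pk_model(
    n_compartments = 2,
    theta = c(CL = 6, V1 = 18, Q = 1.5, V2 = 7),
    omega = c(CL = 0.09, V1 = 0.04),
    residual = list(prop = prop, add = add),
    label = "test 2-cmt"
  )
}

# Model with a single free eta on CL (for grid-search oracles).
cl_only_model <- function(prop = 0.1, add = 0.1) {
  pk_model(
    n_compartments = 1,
    theta = c(CL = 6, V1 = 30),
    omega = c(CL = 0.09),
    residual = list(prop = prop, add = add),
    label = "test CL-only"
  )
}

# Noiseless steady-state peak/trough observations from a 1-cmt individual.
ss_two_samples <- function(CL, V1, amt, tinf, ii, t_peak, t_trough,
                           n_doses = 200) {
  params <- pk_params(CL = CL, V1 = V1)
  ss <- steady_state_conc(params, amt, tinf, ii, offsets = c(t_peak, t_trough),
                          n_doses = n_doses)
  tibble::tibble(time = ss$offset, dv = ss$conc, bloq = FALSE, loq = 0.4)
}
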