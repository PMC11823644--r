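# Illustrative two-compartment tobramycin model ("hennig_like", SYNTHETIC).
# These numbers are realistic placeholders for an adult CF population, NOT
# the published model estimates; transcribe the published values here if you
# hold them. Units: CL, Q in L/h; V1, V2 in L; omega entries are variances of
# log-scale random effects (column-major lower triangle over omega_names);
# sigma.prop is a fraction, sigma.add in mg/L.
model:
  label: hennig_like (synthetic placeholder)
  compartments: 2
  theta:
    CL: 7.0
    V1: 18.5
    Q: 1.6
    V2: 7.5
  omega_names: [CL, V1, Q]
  omega: [0.10, 0.02, 0.0, 0.06, 0.0, 0.16]
  sigma:
    prop: 0.12
    add: 0.25
  covariates:
    - parameter: CL
      covariate: WT
      form: power-normalized
      coef: 0.75
      ref: 70.0
    - parameter: CL
      covariate: CRCL
      form: linear-normalized
      coef: 0.6
      ref: 100.0
    - parameter: V1
      covariate: WT
      form: power-normalized
      coef: 1.0
      ref: 70.0
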