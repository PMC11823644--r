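# Illustrative two-compartment tobramycin model ("alghanem_like", SYNTHETIC).
# Realistic placeholders, NOT the published estimates (see the hennig_like
# file for the key layout). Kept deliberately different from hennig_like —
# fewer variability terms and lower residual error — so matched versus
# mis-specified estimation contrasts are meaningful.
model:
  label: alghanem_like (synthetic placeholder)
  compartments: 2
  theta:
    CL: 5.0
    V1: 13.0
    Q: 0.9
    V2: 5.5
  omega_names: [CL, V1]
  omega: [0.07, 0.01, 0.04]
  sigma:
    prop: 0.08
    add: 0.15
  covariates:
    - parameter: CL
      covariate: WT
      form: power-normalized
      coef: 0.75
      ref: 60.0
    - parameter: CL
      covariate: CRCL
      form: power-normalized
      coef: 0.55
      ref: 100.0
    - parameter: V1
      covariate: WT
      form: linear-normalized
      coef: 1.0
      ref: 60.0
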