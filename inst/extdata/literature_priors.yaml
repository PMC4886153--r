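# Published summaries behind the informative priors: pooled population-PK
# analysis of four intravenous dexmedetomidine studies in 95 children.
# Fixed effects: point estimate with bootstrap 95% CI, standardised to 70 kg
# (CL, Q in L/h; V1, V2 in L; TE50 in postmenstrual weeks; Hill unitless).
# IIV: between-subject variability as %CV of the lognormal distribution.
fixed:
  - parameter: CL
    estimate: 42.1
    ci_lo: 38.7
    ci_hi: 45.8
  - parameter: Q
    estimate: 78.3
    ci_lo: 50.7
    ci_hi: 98.4
  - parameter: V1
    estimate: 56.3
    ci_lo: 44.5
    ci_hi: 67.4
  - parameter: V2
    estimate: 69
    ci_lo: 57.5
    ci_hi: 80.3
  - parameter: TE50
    estimate: 44.5
    ci_lo: 36.8
    ci_hi: 50.3
  - parameter: Hill
    estimate: 2.56
    ci_lo: 1.65
    ci_hi: 3.78
iiv:
  - parameter: CL
    cv_percent: 30.9
  - parameter: Q
    cv_percent: 37
  - parameter: V1
    cv_percent: 61.3
  - parameter: V2
    cv_percent: 47
# Wishart degrees of freedom determined by simulation for ~25% variability
# of the precision diagonal.
rho: 30
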