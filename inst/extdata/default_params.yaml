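# Default model parameters: English major trauma system, costs in 2017/18 GBP.
# Survival-equation coefficients are illustrative, TARN-like values (the
# published TARN 2006 coefficients are not distributed here); replace them
# with the published coefficients for a calibrated analysis.
clinical:
  transfer:
    tp: 0.266    # P(local -> MTC transfer | ISS >= 16, tool positive)
    fn: 0.325    # P(transfer | ISS >= 16, tool negative)
    tn: 0.043    # P(transfer | ISS < 16, tool negative)
    fp: 0.074    # P(transfer | ISS < 16, tool positive)
  rr_death30_local_iss16: 1.25
  rr_death30_local_issLT16: 1.0
  rr_death30_local_iss9to15: 1.0   # scenario lever: partial MTC benefit, ISS 9-15
  p_death_30d_1yr_iss16: 0.036
  rr_1yr_local_iss16: 1.64
  p_death_30d_1yr_issLT16: 0.017
  rr_1yr_local_iss9to15: 1.0       # scenario lever: partial MTC benefit, ISS 9-15
  hr_longterm_iss16: 5.19
  hr_longterm_issLT16: 1.38
utility:
  u_iss9plus: 0.65         # 1-year post-injury utility, ISS >= 9
  ara_constant: 0.9508566  # general-population EQ-5D regression
  ara_age: -0.0002587
  ara_age2: -0.0000332
  ara_male: 0.0212126
  ref_age: 61              # utility-study population: mean age
  ref_male_prop: 0.591     # utility-study population: proportion male
cost:
  transfer_cost: 252
  mtc_admit_iss16: 2819      # MTC best practice tariff, ISS >= 16
  mtc_admit_iss9to15: 1466   # MTC best practice tariff, 9 <= ISS < 16
  blunt_treatment_bands:     # (lo, hi] ISS bands
    - {lo: 0, hi: 9, cost: 6198}
    - {lo: 9, hi: 16, cost: 8989}
    - {lo: 16, hi: 25, cost: 14205}
    - {lo: 25, hi: 75, cost: 21173}
  penetrating_treatment_bands:
    - {lo: 0, hi: 9, cost: 6501}
    - {lo: 9, hi: 15, cost: 6035}
    - {lo: 15, hi: 24, cost: 9453}
    - {lo: 24, hi: 34, cost: 12347}
    - {lo: 34, hi: 75, cost: 16438}
  post_discharge_6mo: 1766
  longterm_mult_iss16: 1.45
  longterm_mult_issLT16: 1.25
economics:
  discount_rate: 0.035
  maicers: [20000, 30000]
  horizon_age_cap: 100
survival_model:
  form: logit_linear
  coefficients:
    intercept: 1.3488
    age: -0.045
    iss: -0.12
    gcs: 0.4
    male: -0.1
tools:
  - {label: "99.8% Sens, 2.5% Spec", sensitivity: 0.998, specificity: 0.025}
  - {label: "94.8% Sens, 18.7% Spec", sensitivity: 0.948, specificity: 0.187}
  - {label: "90.4% Sens, 58.4% Spec", sensitivity: 0.904, specificity: 0.584}
  - {label: "87.5% Sens, 62.8% Spec", sensitivity: 0.875, specificity: 0.628}
  - {label: "74.6% Sens, 65.7% Spec", sensitivity: 0.746, specificity: 0.657}
  - {label: "69.8% Sens, 70.1% Spec", sensitivity: 0.698, specificity: 0.701}
  - {label: "64.2% Sens, 76.1% Spec", sensitivity: 0.642, specificity: 0.761}
  - {label: "57.0% Sens, 80.0% Spec", sensitivity: 0.570, specificity: 0.800}
  - {label: "28.4% Sens, 88.6% Spec", sensitivity: 0.284, specificity: 0.886}
psa:
  se_frac: 0.2    # default SE as a fraction of the mean when no SE is given
  tool_ess: 1000  # effective sample size behind tool sens/spec Beta draws
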