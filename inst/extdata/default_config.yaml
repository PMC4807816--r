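horizon_years: 5.0
cycle_length_days: 21.0
discount_annual: 0.03
half_cycle_correction: no
days_per_month: 30.44
gdp_per_capita: 7679.0
wtp:
  max_gdp_multiple: 3.0
  points: 100.0
psa:
  'n': 1000.0
  seed: 2.0140325e+07
shared:
  followup_cost_per_cycle: 57.96
  docetaxel_ampule_cost: 108.72
  docetaxel_ampules_per_cycle: 6.0
  docetaxel_cycles: 6.0
  u_pfs: 0.673
  u_dp: 0.473
  adr_utility:
    diarrhea: 0.606
    nausea: 0.605
    rash: 0.621
    raised_alt: 0.639
  adr_cost:
    diarrhea: 5.18
    nausea: 13.61
    rash: 5.5
    raised_alt: 216.35
arms:
  icotinib:
    drug_unit_price: 449.8
    drug_units_per_cycle: 3.0
    free_drug_after_cycle: 9.0
    weibull:
      pfs:
        gamma: 0.9359
        log_lambda: -5.0757
      os:
        gamma: 1.1664
        log_lambda: -7.3062
    adr_prob:
      diarrhea: 0.02
      rash: 0.005
      raised_alt: 0.005
      nausea: 0.005
    drug_cost_per_cycle: 1349.4
  gefitinib:
    drug_unit_price: 865.94
    drug_units_per_cycle: 2.1
    free_drug_after_cycle: 7.0
    weibull:
      pfs:
        gamma: 0.94
        log_lambda: -5.2677
      os:
        gamma: 1.1938
        log_lambda: -7.5374
    adr_prob:
      rash: 0.01
      raised_alt: 0.01
    drug_cost_per_cycle: 1818.474
owsa:
  u_pfs:
  - 0.27
  - 0.8
  u_dp:
  - 0.19
  - 0.56
  drug_cost.icotinib:
  - 1349.4
  - 1349.4
  drug_cost.gefitinib:
  - 1610.9
  - 1818.48
  followup_cost:
  - 50.64
  - 57.96
  docetaxel_ampule_cost:
  - 74.96
  - 108.72
  adr_cost.diarrhea:
  - 4.14
  - 6.22
  adr_cost.nausea:
  - 10.89
  - 16.33
  adr_cost.rash:
  - 4.4
  - 6.6
  adr_cost.raised_alt:
  - 173.08
  - 259.62
  adr_prob.icotinib.diarrhea:
  - 0.014
  - 0.026
  discount_annual:
  - 0.0
  - 0.08
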