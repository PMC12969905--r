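strategies:
  lp:
    name: Lenvatinib plus pembrolizumab
    os:
      family: lognormal
      params:
        meanlog: 2.911
        sdlog: 1.245
    pfs:
      family: lognormal
      params:
        meanlog: 2.002
        sdlog: 1.172
    med:
      label:
      - lenvatinib
      - pembrolizumab
      cost_per_cycle:
      - 40656.0
      - 98668.0
      max_cycles:
      - Inf
      - '35'
    pf_nonmed: 22149.0
    pd_cost: 49742.0
    utility_pf: 0.817
    utility_pd: 0.779
    ae:
      name:
      - hypertension
      - diarrhea
      - decreased_appetite
      - weight_loss
      - fatigue
      - proteinuria
      - anemia
      - neutropenia
      risk:
      - 0.392
      - 0.081
      - 0.076
      - 0.108
      - 0.054
      - 0.052
      - 0.069
      - 0.02
      cost:
      - 28.0
      - 25.0
      - 524.0
      - 562.0
      - 0.0
      - 0.0
      - 674.0
      - 2544.0
      disutility:
      - 0.05
      - 0.001
      - 0.002
      - 0.0
      - 0.07
      - 0.0
      - 0.073
      - 0.46
  chemo:
    name: Doxorubicin-based chemotherapy
    os:
      family: loglogistic
      params:
        shape: 1.683
        scale: 11.905
    pfs:
      family: loglogistic
      params:
        shape: 1.885
        scale: 3.956
    med:
      label:
      - doxorubicin
      - other_chemotherapy
      cost_per_cycle:
      - 3779.0
      - 2999.0
      max_cycles:
      - Inf
      - Inf
    pf_nonmed: 22149.0
    pd_cost: 49742.0
    utility_pf: 0.817
    utility_pd: 0.779
    ae:
      name:
      - hypertension
      - diarrhea
      - decreased_appetite
      - weight_loss
      - fatigue
      - proteinuria
      - anemia
      - neutropenia
      risk:
      - 0.026
      - 0.021
      - 0.005
      - 0.003
      - 0.031
      - 0.003
      - 0.155
      - 0.26
      cost:
      - 28.0
      - 25.0
      - 524.0
      - 562.0
      - 0.0
      - 0.0
      - 674.0
      - 2544.0
      disutility:
      - 0.05
      - 0.001
      - 0.002
      - 0.0
      - 0.07
      - 0.0
      - 0.073
      - 0.46
econ:
  cycle_days: 21.0
  horizon_years: 20.0
  disc_effects: 0.03
  disc_costs: 0.03
  wtp: 2917650.0
conversion_factor: 1.0
lp_price_multiplier: 1.0
outcome: qaly
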