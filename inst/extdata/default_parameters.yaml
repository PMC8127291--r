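parameters:
  prevalence:
    base: 0.245
    family: beta
    sd: 0.08
  discount_rate:
    base: 0.05
    family: beta
    ci_low: 0.03
    ci_high: 0.12
  sens_ewgsop:
    base: 1.0
    family: fixed
  sens_sarsamod:
    base: 0.806
    family: beta
    ci_low: 0.767
    ci_high: 0.842
  sens_msra:
    base: 0.804
    family: beta
    sd: 0.08
  sens_sarcf:
    base: 0.168
    family: beta
    ci_low: 0.135
    ci_high: 0.206
  spec_ewgsop:
    base: 0.84
    family: beta
    ci_low: 0.816
    ci_high: 0.862
  spec_sarsamod:
    base: 0.788
    family: beta
    ci_low: 0.75
    ci_high: 0.803
  spec_msra:
    base: 0.604
    family: beta
    ci_low: 0.543
    ci_high: 0.664
  spec_sarcf:
    base: 0.866
    family: beta
    ci_low: 0.843
    ci_high: 0.886
  p_death_healthy:
    base:
    - 0.007031755404011
    - 0.007691412992724
    - 0.008412691294927
    - 0.009201294818848
    - 0.010063445984683
    - 0.011005930132875
    - 0.012036144041204
    - 0.013162148141172
    - 0.01439272261567
    - 0.015737427545848
    - 0.017206667253989
    - 0.018811758959467
    - 0.020565005824518
    - 0.022479774413379
    - 0.024570576519609
    - 0.02685315522894
    - 0.029344574975293
    - 0.032063315211243
    - 0.035029367146645
    - 0.038264332804612
    - 0.041791525396704
    - 0.045636069721864
    - 0.04982500093907
    - 0.054387359643535
    - 0.059354280681985
    family: beta
  p_death_sarc:
    base: 0.132
    family: beta
    sd: 0.013
  p_death_sarc_cvd:
    base: 0.198
    family: beta
    sd: 0.03
  p_death_fracture:
    base: 0.171
    family: beta
    sd: 0.02
  p_fall:
    base: 0.273
    family: beta
    sd: 0.03
  p_fracture_given_fall:
    base: 0.4
    family: beta
    sd: 0.05
  p_cvd:
    base: 0.27
    family: beta
    sd: 0.03
  cost_treatment_annual:
    base: 1119.048000000000002
    family: gamma
    sd: 119.046999999999997
  cost_gait:
    base: 0.714
    family: gamma
  cost_handgrip:
    base: 1.309
    family: gamma
  cost_dxa:
    base: 42.856999999999999
    family: gamma
  cost_msra:
    base: 0.714
    family: gamma
  cost_sarcf:
    base: 0.714
    family: gamma
  cost_sarcf_highrisk:
    base: 44.880000000000003
    family: gamma
  cost_sarsamod:
    base: 1.785
    family: gamma
  cost_ewgsop_stage1:
    base: 2.023
    family: gamma
  cost_ewgsop_stage2:
    base: 42.856999999999999
    family: gamma
  cost_fracture:
    base: 3599.047999999999774
    family: gamma
    sd: 695.073999999999955
  cost_cvd_initial:
    base: 4149.286000000000058
    family: gamma
  cost_cvd_incremental:
    base: 1904.761999999999944
    family: gamma
    sd: 190.475999999999999
  u_healthy:
    base: 0.76
    family: beta
  u_sarc:
    base: 0.68
    family: beta
  u_sarc_fracture:
    base: 0.51
    family: beta
  u_sarc_cvd:
    base: 0.56
    family: beta
  u_sarc_cvd_fracture:
    base: 0.42
    family: beta
  efficacy:
    base: 0.4
    family: beta
    sd: 0.15
  horizon_cycles:
    base: 25.0
    family: fixed
  cycle_length:
    base: 1.0
    family: fixed
  cohort_size:
    base: 1000.0
    family: fixed
  wtp:
    base: 5520.310999999999694
    family: fixed
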