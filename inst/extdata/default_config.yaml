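growth:
  lambda_prolif: 0.14
  delta0: 0.004
  delta_q: 0.003
  k_pq: 0.1
  k_qp: 0.05
  k_cl: 0.05
  v_cell: 1.0e-09
  d_rim: 0.2
  K_max: 1000000000000.0
  alpha_ang: 0.065
  rho_imm: 0.2
  h_imm: 10000000000.0
  d_imm: 0.1
  kappa_I: 0.008
  gamma_drug: 0.01
signaling:
  s0: 1.0
  g_egfr:
    exon19del: 0.5
    L858R: 0.5
  rho_res:
    t790m: 0.9
    kras: 0.85
  surge:
    pERK_EGF:
      A_max: 0.95
      tau: 7.0
    pAKT_EGF:
      A_max: 0.85
      tau: 12.0
    pERK_HGF:
      A_max: 0.7
      tau: 10.0
    pAKT_HGF:
      A_max: 0.9
      tau: 15.0
pk:
  dose: 250.0
  interval: 24.0
  F_bio: 0.6
  ka: 0.5
  ke: 0.014440566261666
  Vd: 1400.0
pd:
  Imax: 0.95
  IC50_base: 0.02
  hill: 1.0
  multipliers:
    exon19del: 1.0
    L858R: 1.6
    t790m: 25.0
    kras: 4.0
    pik3ca: 1.0
regimen:
  start_day: 0.0
  dose_mg: 250.0
  interval_h: 24.0
  end_day: '.inf'
simulation:
  follow_up_months: 30.0
  dt_out_days: 1.0
  pk_mode: average
  rtol: 1.0e-06
  atol: 0.001
  k_cap0: 2.0
clinical:
  reference: nadir
  rel_threshold: 0.2
  abs_threshold_diameter: 0.5
  visit_interval_months: 2.0
vpop:
  size_multiplier: 10.0
  marginals:
    sex:
      type: categorical
      levels:
      - male
      - female
      probs:
      - 0.333333333333333
      - 0.666666666666667
    age:
      type: truncnorm
      mean: 63.0
      sd: 10.287948802930806
      lower: 36.0
      upper: 89.0
    egfr_variant:
      type: categorical
      levels:
      - exon19del
      - L858R
      probs:
      - 0.584905660377358
      - 0.415094339622642
    smoking:
      type: categorical
      levels:
      - never
      - former
      - current
      probs:
      - 0.666666666666667
      - 0.119496855345912
      - 0.213836477987421
    ethnicity:
      type: categorical
      levels:
      - asian
      - non_asian
      probs:
      - 0.553459119496855
      - 0.446540880503145
    stage:
      type: categorical
      levels:
      - IIIb
      - IV
      probs:
      - 0.018867924528302
      - 0.981132075471698
    kras:
      type: categorical
      levels:
      - yes
      - no
      probs:
      - 0.025
      - 0.975
    pik3ca:
      type: categorical
      levels:
      - yes
      - no
      probs:
      - 0.04
      - 0.96
    r0:
      type: lognormal
      meanlog: 0.405465108108164
      sdlog: 0.25
      lower: 0.7
      upper: 4.0
    prolif_frac0:
      type: truncnorm
      mean: 0.6
      sd: 0.1
      lower: 0.2
      upper: 0.9
    f_res:
      type: lognormal
      meanlog: -5.115995809754082
      sdlog: 1.3
      lower: 1.0e-06
      upper: 0.3
    m_prolif:
      type: truncnorm
      mean: 0.0
      sd: 0.2
      lower: -0.5
      upper: 0.5
    lambda_prolif:
      type: lognormal
      meanlog: -1.966112856372833
      sdlog: 0.15
      lower: 0.03
      upper: 0.5
    delta0:
      type: lognormal
      meanlog: -5.521460917862246
      sdlog: 0.2
      lower: 0.0005
      upper: 0.05
    alpha_ang:
      type: lognormal
      meanlog: -2.7333680090865
      sdlog: 0.5
      lower: 0.008
      upper: 0.4
    rho_imm:
      type: lognormal
      meanlog: -1.6094379124341
      sdlog: 0.8
      lower: 0.01
      upper: 2.0
    kappa_I:
      type: lognormal
      meanlog: -4.828313737302302
      sdlog: 0.8
      lower: 0.0003
      upper: 0.08
    d_rim:
      type: lognormal
      meanlog: -1.6094379124341
      sdlog: 0.15
      lower: 0.05
      upper: 0.6
validation:
  n_bootstrap_pi: 1000.0
  n_lr_tests: 7000.0
  level: 0.95
  coverage_threshold: 80.0
  lr_threshold: 80.0
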