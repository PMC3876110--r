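physical:
  F: 96485.0
  R_gas: 8314.0
  temp: 310.0
geometry:
  cm_tot: 153.400000000000006
  area_frac_t: 0.56
  v_myo: 25.84
  v_nsr: 2.1
  v_jsr: 0.16
  v_ds: 0.0012
  v_tt: 1.9323
  tt_radius: 0.45
  v_cleft: 3.5
bulk:
  na_b: 140.0
  k_b: 5.4
  ca_b: 2.0
fractions:
  f_na_t: 0.56
  f_naps_t: 0.56
  f_cal_t: 0.64
  f_kto_t: 0.56
  f_kr_t: 0.56
  f_ks_t: 0.56
  f_k1_t: 0.67
  f_bna_t: 0.56
  f_kna_t: 0.56
  f_nsca_t: 0.56
  f_naca_t: 0.56
  f_nak_t: 0.56
  f_pca_t: 0.2
  f_cab_t: 0.56
exchange:
  tau_ca_ct: 240.0
  tau_k_ct: 97.0
  tau_na_ct: 143.0
  tau_ca_cb: 24700.0
  tau_k_cb: 10000.0
  tau_na_cb: 14300.0
  d_rad_ca: 5.0e-09
  d_rad_k: 1.25e-08
  d_rad_na: 8.400000000000001e-09
currents:
  g_na: 3200.0
  g_naps: 0.15
  p_cal: 0.0158
  g_kto: 45.0
  g_kr: 23.0
  g_ks: 45.0
  g_k1: 829.0
  g_bna: 0.1843
  g_bca: 0.3169
  g_kna: 3.0
  kd_kna: 66.0
  p_nsca: 2.0e-06
  km_nsca: 0.0012
  k_naca: 153400.0
  gamma_naca: 0.35
  km_nai_naca: 87.5
  km_ca_naca: 1.38
  ksat_naca: 0.1
  alpha_naca: 2.5
  i_nak_max: 128.0
  km_k_nak: 1.0
  km_na_nak: 10.0
  pk_na_ks: 0.03
  g_pca: 250.0
  km_pca: 0.0005
  tau_f_scale: 1.0
  nak_v_flat: 0.8
sr:
  v1_ryr: 1.8
  ka_p: 12150000000.0
  ka_m: 0.576
  kb_p: 4050000.0
  kb_m: 1.93
  kc_p: 0.1
  kc_m: 0.0008
  vmax_f: 0.000115
  vmax_r: 0.0001845
  k_fb: 0.000114
  k_rb: 3.29
  n_fb: 2.0
  n_rb: 1.0
  tau_tr: 0.5747
  tau_xfer: 26.699999999999999
buffers:
  cmdn_tot: 0.05
  cmdn_kon: 34.0
  cmdn_koff: 0.0809
  htrpn_tot: 0.14
  htrpn_kon: 20.0
  htrpn_koff: 6.600000000000001e-05
  ltrpn_tot: 0.07
  ltrpn_kon: 40.0
  ltrpn_koff: 0.04
  csqn_tot: 15.0
  csqn_kon: 0.1
  csqn_koff: 0.08
stimulus:
  stim_amp: -1800.0
  stim_dur: 3.0
clamp:
  clamp_tub: 0.0
  clamp_cleft: 0.0
  fix_naki: 0.0
clamp_mode: free
meta:
  calibrated:
  - v_tt
  - tt_radius
  - v_cleft
  - f_k1_t
  - tau_k_ct
  - tau_na_ct
  - tau_ca_cb
  - tau_k_cb
  - tau_na_cb
  - d_rad_ca
  - d_rad_k
  - d_rad_na
  - g_naps
  - p_cal
  - g_bna
  - g_bca
  - g_kna
  - p_nsca
  - k_naca
  - i_nak_max
  - g_pca
  - tau_f_scale
  - nak_v_flat
  - vmax_f
  - vmax_r
  - tau_xfer
  - stim_amp
  layout_version: 1
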