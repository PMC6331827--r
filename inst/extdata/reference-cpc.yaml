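optics:
  kappa_m2kg: 174.7
  sigma_m2kg: 1295.8
  p_f: 0.11
  p_b: 0.71
  p_s: 0.045
geometry:
  tube_radius_m: 0.0165
  delta_m: 0.033
  tube_length_m: 1.2
  n_tubes: 10
  theta_a_deg: 90.0
  aperture_width_m: 0.1
  optical_efficiency: 1.0
flow:
  flow_L_min: 30.2
  diameter_mm: 33.0
  kinematic_viscosity_m2_s: 1.0e-06
operation:
  I0_W_m2: 30.0
  c_cat_g_L: 0.6
  V_T_L: 40.0
kinetics:
  slope: 348947.0
  intercept: 25773.0
  vrpa_W: 4.86
  m_exp: 0.5
  reference_removal:
    toc0_ppm: 213.6
    removal_pct: 31.1
    t30w_min: 42.0
adsorption:
  q0_mg_g: 1.52
  K_ads_per_ppm: 0.00442
simulation:
  n_subreactors: 100
  n_r: 50
  n_theta: 72
  illumination: calibrated_cpc
seed: 1
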