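species: mouse
context:
  body_weight: 0.02
  V_P: 1.0
  V_pc: 0.1
  plasma_flow:
    mode: exponential
    a: 2843.0
    b: 0.65
  surface_area:
    mode: exponential
    a1: 0.26
    b1: 4.5
    a2: 138.0
    b2: 0.04
biological:
  A_B_E: 11.9
  A_M_E: 10.52
  K_B_E: 16.03
  delta_E: 60.48
  g_E0: 36.3
  C_E0: 0.58
  A_E_P: 3.32
  A_Ab_P: 1.79
  K_E_P: 8.1
  delta_P: 60.48
  g_P0: 10.44
  C_P0: 0.21
  A_E_B: 4.5
  K_E_B: 8.78
  A_E_D: 0.1
  K_E_D: 10.0
  sigma: 3.1
  B_star: 2.21
  delta_B_I: 3.0
  eps_P: 1.9
  delta_B_C: 2.46
  phi_pore: 1700.0
  L: 0.01
  eta_B_B: 7.42
  eta_B_I: 3.5
  B_0: 0.001
  f_v: 0.17
  f_c: 0.4
  f_cy: 0.4
  dx: 0.0005
therapy:
  phi_NP: 70.0
  delta_NP: 7.7
  M_0: 0.007
  k_rel: 0.99
  k_endo: 10.0
  alpha_NP: 1.86e-09
  EC50_M: 2.34
  g_M0: 0.033
  eps_B: 1.0
  delta_M: 4.851
  Cl_dox: 8400.0
  V_D_dox: 734.0
  delta_D: 2.0
  EC50_D: 25.0
  phi_Ab: 10.0
  delta_Ab: 1.21
  Cl_Ab: 3.07
  V_D_Ab: 1.97
  EC50_Ab: 0.0446
  k_abs: 100.0
  D_NP: 0.0112
  D_Ab: 0.0784
  D_dox: 0.4933
options:
  plasma_volume_mode: vp
  B_guard: 1.0e-12
units:
  time: weeks
  volume: mL
  concentration: nM
  diameter: nm
  length: cm
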