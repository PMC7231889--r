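# Baseline ventricular-like hiPSC-CM model parameter set (reference
# conditions: 37 degC, Nao 151 mM, Ko 5.4 mM, Cao 1.8 mM).
#
# Units: conductances S/F except g_CaL (m^3 F^-1 s^-1), pump/exchanger
# maxima A/F, SR fluxes mM/s, capacitance F, volumes um^3, concentrations mM,
# time constants s, Ca_half_rel uM.
environment:
  temperature: 37.0
  Nao: 151.0
  Ko: 5.4
  Cao: 1.8
constants:
  Ki: 150.0
  Cm: 9.87109e-11
  Vc: 8800.0
  V_SR: 583.73
  g_Na: 5500.0
  g_NaL: 17.25
  g_f: 30.10312
  fNa_f: 0.37
  g_CaL: 8.98113008e-5
  g_to: 29.9038
  g_Ks: 2.041
  g_Kr: 32.2560036
  g_K1: 24.0
  k_NCX: 8000.0
  P_NaK: 2.74240
  g_PCa: 0.4125
  g_bNa: 0.95
  g_bCa: 0.727272
  g_rel: 62.5434
  V_up: 0.82205
  V_leak: 4.7279e-4
  K_up: 3.8e-4
  RyRa1: 0.05354
  RyRa2: 0.0488
  Ca_half_rel: 0.02427
  RyRohalf: 0.01042
  RyRchalf: 0.00144
  tau_adapt_rel: 0.6
  tau_act_rel: 0.01875
  tau_inact_rel: 0.0875
  Buf_C: 0.25
  Buf_SR: 10.0
  Kbuf_C: 0.001
  Kbuf_SR: 0.3
  KmCa: 1.38
  KmNai: 87.5
  Ksat: 0.1
  gamma_NCX: 0.35
  alpha_NCX: 2.16659
  Km_K: 1.0
  Km_Na: 40.0
  KPCa: 0.0005
  PkNa: 0.03
  L0: 0.025
  Q_Kr: 2.3
  Vh_hL: 87.61
  tau_hL: 0.2
# Fold-change of gating kinetics per 10 degC; families without an entry are
# not rescaled beyond their explicit temperature terms.
q10:
  I_Na: 2.1
  I_NaL: 2.1
  I_CaL: 2.1
  I_Kr: 2.1
  I_Ks: 2.1
  I_to: 2.1
  I_f: 2.1
  I_rel: 2.1
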