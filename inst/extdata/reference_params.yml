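k_m0_L: 0.032
k_m0_T: 0.119
k_m_L: 8.3
k_m_T: 2.06
k_p_L: 0.9726
k_p_T: 1.17
g_m_L: 0.1386
g_m_T: 0.1386
g_p_L: 0.0165
g_p_T: 0.0165
theta_LacI: 31.94
theta_TetR: 30.0
theta_aTc: 11.65
theta_IPTG: 0.0906
eta_LacI: 2.0
eta_TetR: 2.0
eta_aTc: 2.0
eta_IPTG: 2.0
exchange:
  variant: asymmetric
  k_aTc_in: 0.162
  k_aTc_out: 0.02
  k_IPTG_in: 0.0275
  k_IPTG_out: 0.111
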