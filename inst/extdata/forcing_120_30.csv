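# period_min: 150
t_start_min,u_aTc_ng_per_ml,u_IPTG_mM
0,0,0.5
120,50,0
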