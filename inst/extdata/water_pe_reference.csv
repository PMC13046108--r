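energy_MeV,tau_over_rho_cm2_g
0.1,0.00276
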