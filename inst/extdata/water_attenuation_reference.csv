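energy_MeV,mu_over_rho_cm2_g
0.1,0.1657
1.0,0.0707
6.0,0.0277
18.0,0.0170
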