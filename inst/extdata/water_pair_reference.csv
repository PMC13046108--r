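energy_MeV,kappa_over_rho_cm2_g
6.0,0.0030
18.0,0.0059
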