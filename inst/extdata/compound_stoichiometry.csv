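compound,element,n_atoms,density_g_cm3
Fe2O3,Fe,2,5.3
Fe2O3,O,3,5.3
Al(OH)3,Al,1,2.4
Al(OH)3,O,3,2.4
Al(OH)3,H,3,2.4
carbon-black,C,1,1.8
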