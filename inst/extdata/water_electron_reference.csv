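quantity,energy_MeV,value,units
collision_stopping_power,0.1,4.115,MeV_cm2_g
collision_stopping_power,1.0,1.849,MeV_cm2_g
csda_range,6.0,3.052,g_cm2
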