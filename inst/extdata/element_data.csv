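element,Z,atomic_mass,I_eV
H,1,1.008,19.2
C,6,12.011,81.0
N,7,14.007,82.0
O,8,15.999,106.0
Na,11,22.990,149.0
Al,13,26.982,166.0
P,15,30.974,173.0
S,16,32.06,180.0
K,19,39.098,190.0
Ca,20,40.078,191.0
V,23,50.942,245.0
Cr,24,51.996,257.0
Fe,26,55.845,286.0
Co,27,58.933,297.0
Ni,28,58.693,311.0
Cu,29,63.546,322.0
Zn,30,65.38,330.0
Cd,48,112.414,469.0
Ba,56,137.327,491.0
Hg,80,200.592,800.0
Pb,82,207.2,823.0
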